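#' Per-cell mitochondrial UMI fraction
#'
#' Sum of mitochondrial UMIs over total UMIs per cell. Cells with zero total
#' counts get a fraction of 0 (they are flagged in the attribute
#' `zero_total`). Mitochondrial genes are taken from `rowData(sce)$is_mito`
#' when present, otherwise detected by a case-insensitive symbol prefix.
#'
#' @param sce a [SingleCellExperiment] with a `counts` assay.
#' @param mitoPrefix symbol prefix marking mitochondrial genes when no
#'   `is_mito` column exists (default `"MT-"`).
#' @return named numeric vector, one fraction per cell.
#' @export
mitoFraction <- function(sce, mitoPrefix = "MT-") {
  counts <- assay(sce, "counts")
  isMito <- rowData(sce)$is_mito
  if (is.null(isMito))
    isMito <- startsWith(toupper(rownames(sce)), toupper(mitoPrefix))
  tot <- Matrix::colSums(counts)
  mito <- Matrix::colSums(counts[isMito, , drop = FALSE])
  frac <- ifelse(tot > 0, mito / tot, 0)
  frac <- setNames(as.numeric(frac), colnames(sce))
  attr(frac, "zero_total") <- colnames(sce)[tot == 0]
  frac
}

#' Single-cell QC filter cascade
#'
#' Applies the three-step filter in a fixed order, recomputing detection and
#' mitochondrial fractions after each step, with strict inequalities
#' throughout ("less than" / "more than"):
#' \enumerate{
#'   \item drop cells with fewer than `minGenes` detected genes (count > 0);
#'   \item drop genes detected in fewer than `minCells` of the remaining
#'     cells;
#'   \item drop cells with more than `maxGenes` detected genes (recomputed on
#'     the filtered gene panel) or a mitochondrial UMI fraction above
#'     `maxMito`.
#' }
#' The order is part of the contract: running the gene filter first can give
#' a different result, so it is fixed (and reported) rather than inferred.
#' Applying the cascade twice with the same thresholds removes nothing the
#' second time.
#'
#' @param sce a [SingleCellExperiment] with a `counts` assay of non-negative
#'   integer UMIs.
#' @param minGenes,minCells,maxGenes,maxMito thresholds; defaults 200, 3,
#'   5000 and 0.30.
#' @param mitoPrefix passed to [mitoFraction()].
#' @return list with `sce` (the filtered dataset) and `report`, a
#'   [QCReport-class] with per-step removal counts.
#' @examples
#' sim <- simulateSC(nLowQuality = c(few_genes = 2, many_genes = 3,
#'                                   high_mito = 4), seed = 1)
#' th <- sim$truth@thresholds
#' qc <- qcFilter(sim$sce, th$minGenes, th$minCells, th$maxGenes, th$maxMito)
#' qc$report
#' @export
qcFilter <- function(sce, minGenes = 200, minCells = 3, maxGenes = 5000,
                     maxMito = 0.30, mitoPrefix = "MT-") {
  stopifnot(minGenes > 0, minCells > 0, maxGenes > 0, maxMito > 0)
  if (ncol(sce) == 0 || nrow(sce) == 0) stop("empty input matrix")
  nCellsIn <- ncol(sce); nGenesIn <- nrow(sce)

  # step 1: cells expressing too few genes
  detected <- Matrix::colSums(assay(sce, "counts") > 0)
  drop1 <- detected < minGenes
  if (all(drop1)) stop("QC step 1 (min genes per cell) removed every cell")
  sce <- sce[, !drop1]

  # step 2: genes detected in too few cells (detection recomputed)
  perGene <- Matrix::rowSums(assay(sce, "counts") > 0)
  drop2 <- perGene < minCells
  if (all(drop2)) stop("QC step 2 (min cells per gene) removed every gene")
  sce <- sce[!drop2, ]

  # step 3: cells with too many genes or excessive mito fraction
  detected <- Matrix::colSums(assay(sce, "counts") > 0)
  frac <- mitoFraction(sce, mitoPrefix)
  drop3 <- detected > maxGenes | frac > maxMito
  if (all(drop3)) stop("QC step 3 (max genes / mito fraction) removed every cell")
  sce <- sce[, !drop3]

  report <- new("QCReport",
    nCellsIn = nCellsIn, nGenesIn = nGenesIn,
    removedCellsMinGenes = sum(drop1),
    removedGenesMinCells = sum(drop2),
    removedCellsMaxGenesOrMito = sum(drop3),
    nCellsOut = ncol(sce), nGenesOut = nrow(sce),
    thresholds = list(minGenes = minGenes, minCells = minCells,
                      maxGenes = maxGenes, maxMito = maxMito))
  validObject(report)
  list(sce = sce, report = report)
}

#' Summarize a gene's expression by cell group
#'
#' Per group (cell type or condition): number of cells, fraction of cells
#' expressing the gene (count > 0) and the mean count among expressing
#' cells. Groups with no expressing cell report a mean of 0 and are flagged.
#'
#' @param sce a [SingleCellExperiment] with a `counts` assay.
#' @param gene a gene id present in `rownames(sce)`.
#' @param groupBy a `colData` column name, `"cell_type"` (default) or
#'   `"condition"`.
#' @return data.frame ordered by group label: `group`, `n_cells`,
#'   `fraction_expressing`, `mean_count_in_expressing`, `no_expressing`.
#' @export
expressionByGroup <- function(sce, gene, groupBy = "cell_type") {
  if (!(gene %in% rownames(sce)))
    stop(sprintf("gene '%s' not found", gene))
  grp <- colData(sce)[[groupBy]]
  if (is.null(grp)) stop(sprintf("colData column '%s' not found", groupBy))
  x <- as.numeric(assay(sce, "counts")[gene, ])
  levs <- sort(unique(as.character(grp)))
  rows <- lapply(levs, function(g) {
    xi <- x[grp == g]
    expres <- xi > 0
    data.frame(group = g, n_cells = length(xi),
               fraction_expressing = mean(expres),
               mean_count_in_expressing = if (any(expres))
                 mean(xi[expres]) else 0,
               no_expressing = !any(expres))
  })
  do.call(rbind, rows)
}
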