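# Readers and writers for the plain-text formats the pipeline exchanges:
# genes-by-samples TSV matrices with metadata, SIF-style network exports,
# two/three-column edge lists, and MatrixMarket sparse counts.

#' Read a genes-by-samples expression TSV
#'
#' First column gene ids, remaining columns samples (header row).
#'
#' @param path path to the TSV.
#' @return numeric matrix with gene rownames.
#' @export
readExprTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' Write a genes-by-samples expression TSV
#'
#' @param mat numeric matrix with gene rownames.
#' @param path output path.
#' @export
writeExprTSV <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a bulk expression SummarizedExperiment from plain tables
#'
#' @param mat numeric genes-by-samples matrix (e.g. from [readExprTSV()] or
#'   [collapseProbes()]).
#' @param group character vector or named vector of sample group labels.
#' @param biotype character vector or named vector of gene biotypes
#'   (`lncRNA`/`mRNA`).
#' @return a [SummarizedExperiment] accepted by [runComparison()] and
#'   [buildNetwork()].
#' @export
makeBulkExperiment <- function(mat, group, biotype) {
  if (!is.null(names(group))) group <- group[colnames(mat)]
  if (!is.null(names(biotype))) biotype <- biotype[rownames(mat)]
  stopifnot(length(group) == ncol(mat), length(biotype) == nrow(mat),
            !anyDuplicated(rownames(mat)), !anyDuplicated(colnames(mat)))
  SummarizedExperiment(
    assays = list(exprs = mat),
    rowData = S4Vectors::DataFrame(biotype = as.character(biotype),
                                   row.names = rownames(mat)),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(mat)))
}

#' Write a co-expression network as SIF plus attribute tables
#'
#' Produces `<prefix>.sif` (source, interaction `coexpr_pos`/`coexpr_neg`,
#' target), `<prefix>_edges.tsv` (r, p per edge) and `<prefix>_nodes.tsv`
#' (biotype, regulation, degree) — loadable by standard graph viewers.
#'
#' @param net a [CoexprNetwork-class].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
writeNetworkSIF <- function(net, prefix) {
  ed <- netEdges(net); nd <- netNodes(net)
  sif <- data.frame(source = ed$lnc,
                    interaction = ifelse(ed$sign == "positive",
                                         "coexpr_pos", "coexpr_neg"),
                    target = ed$mrna)
  paths <- paste0(prefix, c(".sif", "_edges.tsv", "_nodes.tsv"))
  utils::write.table(sif, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(as.data.frame(ed), paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(nd), paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a two/three-column edge list TSV
#'
#' Used for the PPI and TF-target layers: columns source, target and an
#' optional provenance label; a header row is expected.
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readEdgeList <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = "character")
}

#' Write a single-cell dataset as MatrixMarket plus metadata TSVs
#'
#' `<prefix>.mtx` (genes x cells triplets), `<prefix>_genes.tsv` and
#' `<prefix>_cells.tsv`.
#'
#' @param sce a [SingleCellExperiment] with a `counts` assay.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
writeSCMatrix <- function(sce, prefix) {
  paths <- paste0(prefix, c(".mtx", "_genes.tsv", "_cells.tsv"))
  Matrix::writeMM(methods::as(assay(sce, "counts"), "CsparseMatrix"),
                  paths[1])
  utils::write.table(data.frame(gene = rownames(sce),
                                as.data.frame(rowData(sce))),
                     paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell = colnames(sce),
                                as.data.frame(colData(sce))),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a single-cell dataset from MatrixMarket plus metadata TSVs
#'
#' Inverse of [writeSCMatrix()].
#'
#' @param prefix path prefix used when writing.
#' @return a [SingleCellExperiment].
#' @export
readSCMatrix <- function(prefix) {
  counts <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")),
                        "CsparseMatrix")
  genes <- utils::read.delim(paste0(prefix, "_genes.tsv"))
  cells <- utils::read.delim(paste0(prefix, "_cells.tsv"))
  dimnames(counts) <- list(genes$gene, cells$cell)
  SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(genes[, -1, drop = FALSE],
                                   row.names = genes$gene),
    colData = S4Vectors::DataFrame(cells[, -1, drop = FALSE],
                                   row.names = cells$cell))
}
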