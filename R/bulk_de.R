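#' Collapse probe-level expression to gene level
#'
#' Probes without a gene id and probes mapping to more than one gene id are
#' deleted; when several probes map to the same gene, the gene's expression
#' is the arithmetic mean of those probes' rows.
#'
#' @param probeMatrix numeric probes-by-samples matrix with probe rownames.
#' @param probeMap named character vector, probe id -> gene id, covering a
#'   subset of probes. Probes absent from the map are dropped.
#' @param multiTargetProbes character vector of probes known to map to more
#'   than one gene id; always dropped.
#' @return numeric genes-by-samples matrix with unique gene rownames.
#' @examples
#' m <- rbind(p1 = c(1, 3), p2 = c(3, 5), p3 = c(7, 7))
#' collapseProbes(m, c(p1 = "gA", p2 = "gA", p3 = "gB"))
#' @export
collapseProbes <- function(probeMatrix, probeMap,
                           multiTargetProbes = character()) {
  if (is.null(rownames(probeMatrix)))
    stop("'probeMatrix' must have probe rownames")
  keep <- rownames(probeMatrix) %in% names(probeMap) &
    !(rownames(probeMatrix) %in% multiTargetProbes)
  if (!any(keep))
    stop("no probes left after removing unmapped and multi-target probes")
  m <- probeMatrix[keep, , drop = FALSE]
  gene <- probeMap[rownames(m)]
  collapsed <- rowsum(m, group = gene, reorder = TRUE) /
    as.vector(table(gene)[sort(unique(gene))])
  rownames(collapsed) <- sort(unique(gene))
  collapsed
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classic equal-variance two-sample t statistic with
#' `df = length(x) + length(y) - 2` and a two-sided p-value from the t
#' distribution; Welch's unequal-variance form is available via
#' `varEqual = FALSE`. Degenerate inputs follow a fixed contract: if both
#' groups are constant and equal, `t = 0, p = 1`; if constant and unequal,
#' `p = 0` with `degenerate = TRUE` and a signed infinite t.
#'
#' @param x,y numeric vectors (case and control), each with >= 2 finite
#'   values.
#' @param varEqual pooled (Student) when `TRUE` (default), Welch otherwise.
#' @return list with `t`, `p`, `df`, `meanDiff` (`mean(x) - mean(y)`) and
#'   `degenerate`.
#' @examples
#' tTestTwoGroup(c(4, 5, 6), c(1, 2, 3))
#' @importFrom stats pt var
#' @export
tTestTwoGroup <- function(x, y, varEqual = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 finite values")
  nx <- length(x); ny <- length(y)
  d <- mean(x) - mean(y)
  vx <- var(x); vy <- var(y)
  if (varEqual) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- if (se > 0) se^4 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
          else nx + ny - 2
  }
  if (se == 0) {
    if (d == 0) return(list(t = 0, p = 1, df = df, meanDiff = 0,
                            degenerate = FALSE))
    return(list(t = sign(d) * Inf, p = 0, df = df, meanDiff = d,
                degenerate = TRUE))
  }
  t <- d / se
  list(t = t, p = 2 * pt(-abs(t), df), df = df, meanDiff = d,
       degenerate = FALSE)
}

# vectorised pooled t over matrix rows; same degenerate contract as
# tTestTwoGroup
rowPooledT <- function(mat, caseIdx, ctrlIdx) {
  nx <- length(caseIdx); ny <- length(ctrlIdx)
  xm <- rowMeans(mat[, caseIdx, drop = FALSE])
  ym <- rowMeans(mat[, ctrlIdx, drop = FALSE])
  xv <- apply(mat[, caseIdx, drop = FALSE], 1L, var)
  yv <- apply(mat[, ctrlIdx, drop = FALSE], 1L, var)
  df <- nx + ny - 2
  se <- sqrt((((nx - 1) * xv + (ny - 1) * yv) / df) * (1 / nx + 1 / ny))
  d <- xm - ym
  tSafe <- d / pmax(se, .Machine$double.xmin)
  t <- unname(ifelse(se > 0, tSafe, ifelse(d == 0, 0, sign(d) * Inf)))
  p <- unname(ifelse(se > 0, 2 * pt(-abs(tSafe), df), ifelse(d == 0, 1, 0)))
  d <- unname(d); se <- unname(se)
  list(t = t, p = p, meanDiff = d, degenerate = se == 0 & d != 0)
}

#' Differential expression for one case/control comparison
#'
#' Runs the pooled two-sample Student's t-test on every gene of a log-scale
#' expression matrix and flags significance at a raw (unadjusted) p-value
#' threshold, i.e. `significant <=> p < alpha` with a strict inequality.
#' A Benjamini-Hochberg adjusted column is available via `adjust = TRUE`
#' (significance then uses the adjusted p), but the default follows the raw
#' threshold convention of two-group IPF comparisons.
#'
#' @param expr a [SummarizedExperiment] with a log-scale assay (the first
#'   assay is used), `rowData(expr)$biotype` and `colData(expr)$group`, e.g.
#'   from [simulateBulk()] or assembled from [collapseProbes()] output.
#' @param caseGroup,controlGroup group labels present in
#'   `colData(expr)$group`, each with >= 2 samples.
#' @param alpha significance level on the two-sided p (default 0.01).
#' @param adjust apply BH adjustment before thresholding (default `FALSE`).
#' @return an [S4Vectors::DataFrame] with one row per gene: `gene`,
#'   `biotype`, `mean_diff` (case minus control), `t_stat`, `p`,
#'   `significant`, `direction` (`up` iff `mean_diff > 0`), `degenerate`.
#'   The comparison id, groups and alpha are stored in `metadata()`.
#' @examples
#' sim <- simulateBulk(nGenes = 60, nLnc = 6, seed = 1)
#' deg <- runComparison(sim$expr, "IPF", "normal")
#' head(deg)
#' @export
runComparison <- function(expr, caseGroup, controlGroup, alpha = 0.01,
                          adjust = FALSE) {
  grp <- colData(expr)$group
  if (is.null(grp)) stop("colData(expr)$group is required")
  for (g in c(caseGroup, controlGroup))
    if (sum(grp == g) < 2L)
      stop(sprintf("group '%s' absent or has fewer than 2 samples", g))
  mat <- assay(expr, 1L)
  res <- rowPooledT(mat, which(grp == caseGroup), which(grp == controlGroup))
  p_use <- if (adjust) stats::p.adjust(res$p, method = "BH") else res$p
  bt <- rowData(expr)$biotype
  out <- S4Vectors::DataFrame(
    gene = rownames(mat),
    biotype = if (is.null(bt)) NA_character_ else bt,
    mean_diff = res$meanDiff,
    t_stat = res$t,
    p = res$p,
    significant = p_use < alpha,
    direction = ifelse(res$meanDiff > 0, "up", "down"),
    degenerate = res$degenerate)
  if (any(res$degenerate))
    warning("zero-variance genes with unequal means: ",
            paste(utils::head(out$gene[res$degenerate], 5), collapse = ", "),
            if (sum(res$degenerate) > 5) ", ..." else "")
  S4Vectors::metadata(out) <- list(
    comparison = paste(caseGroup, "vs", controlGroup),
    case = caseGroup, control = controlGroup,
    alpha = alpha, adjusted = adjust)
  out
}

#' Intersect differential-expression comparisons
#'
#' IPF-related genes are those significant in every supplied comparison.
#' The intersection is split by biotype into lncRNAs and mRNAs. Genes
#' significant everywhere but with opposite directions across comparisons
#' are reported in `discordant` and still included in the sets (no
#' concordance requirement is imposed).
#'
#' @param tables list of DEG tables from [runComparison()], all over the
#'   same gene universe.
#' @return list with `lnc`, `mrna`, `all` (character vectors of intersected
#'   significant genes) and `discordant`.
#' @export
intersectComparisons <- function(tables) {
  if (!length(tables)) stop("at least one DEG table is required")
  genes <- tables[[1]]$gene
  for (tb in tables)
    if (!setequal(tb$gene, genes) || length(tb$gene) != length(genes))
      stop("DEG tables cover different gene universes")
  sig <- Reduce(intersect, lapply(tables, function(tb) tb$gene[tb$significant]))
  dir <- vapply(tables,
                function(tb) setNames(tb$direction, tb$gene)[sig],
                character(length(sig)))
  dir <- matrix(dir, nrow = length(sig))
  discordant <- sig[apply(dir, 1L, function(d) length(unique(d)) > 1L)]
  bt <- setNames(tables[[1]]$biotype, tables[[1]]$gene)[sig]
  list(lnc = sig[bt == "lncRNA"], mrna = sig[bt == "mRNA"],
       all = sig, discordant = discordant)
}
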