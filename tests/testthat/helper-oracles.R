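# Independent oracles used to cross-check the package's statistics.
# Each oracle deliberately takes a different computational route from the
# implementation it checks:
#  - pooled t / Pearson p: stats::t.test / stats::cor.test (the package uses
#    its own vectorised closed-form transforms);
#  - BH: a hand-written step-up pass (the package delegates to p.adjust);
#  - hypergeometric upper tail: exact combinatorial enumeration (the package
#    delegates to phyper);
#  - network construction: a double loop of cor.test calls over all pairs.

oracleT <- function(x, y) {
  o <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(o$statistic), p = o$p.value)
}

oracleCor <- function(x, y) {
  o <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(o$estimate), p = o$p.value)
}

# step-up BH by hand: sort, scale by m/i, cumulative min from the right
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  pmin(adj, 1)[order(o)]
}

# P(X >= k), X ~ Hypergeom(N, K, n), by direct enumeration of the pmf
oracleHyper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# all-pairs re-computation of the thresholded bipartite network
oracleNetwork <- function(mat, lncSet, mrnaSet, rT = 0.8, pT = 0.01) {
  out <- list()
  for (l in lncSet) for (m in mrnaSet) {
    ct <- stats::cor.test(mat[l, ], mat[m, ])
    if (abs(ct$estimate) > rT && ct$p.value < pT)
      out[[length(out) + 1L]] <- data.frame(
        lnc = l, mrna = m, r = unname(ct$estimate), p = ct$p.value)
  }
  if (!length(out))
    return(data.frame(lnc = character(), mrna = character(),
                      r = numeric(), p = numeric()))
  df <- do.call(rbind, out)
  df[order(df$lnc, df$mrna), , drop = FALSE]
}

# build a CoexprNetwork from a hand-written edge table (for testing the
# degree/hub operations in isolation)
makeNet <- function(edges, lncIds = NULL, rT = 0.8, pT = 0.01) {
  if (is.null(lncIds)) lncIds <- unique(edges$lnc)
  ids <- sort(unique(c(edges$lnc, edges$mrna)))
  deg <- table(factor(c(edges$lnc, edges$mrna), levels = ids))
  new("CoexprNetwork",
      edges = S4Vectors::DataFrame(
        lnc = edges$lnc, mrna = edges$mrna,
        r = if (is.null(edges$r)) rep(0.9, nrow(edges)) else edges$r,
        p = if (is.null(edges$p)) rep(1e-4, nrow(edges)) else edges$p,
        sign = rep("positive", nrow(edges))),
      nodes = S4Vectors::DataFrame(
        id = ids,
        biotype = ifelse(ids %in% lncIds, "lncRNA", "mRNA"),
        regulation = rep(NA_character_, length(ids)),
        degree = as.integer(deg[ids])),
      thresholds = list(r = rT, p = pT))
}

# tiny SingleCellExperiment from a dense count matrix
makeSCE <- function(counts, cellType = NULL, condition = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(cellType)) cd$cell_type <- cellType
  if (!is.null(condition)) cd$condition <- condition
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = cd)
}
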