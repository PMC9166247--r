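#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with the usual t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom;
#' `|r| = 1` returns `p = 0`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, both non-constant.
#' @return list with `r` and `p`.
#' @examples
#' pearsonWithP(c(1, 2, 3, 4), c(1, 2, 3, 5))
#' @importFrom stats cor sd
#' @export
pearsonWithP <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop("at least 3 paired observations are required")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- cor(x, y)
  list(r = r, p = corPValue(r, n))
}

# two-sided p for a Pearson r at sample size n (vectorised; keeps dim)
corPValue <- function(r, n) {
  r <- pmax(pmin(r, 1), -1)
  p <- ifelse(abs(r) >= 1, 0,
              2 * pt(-abs(r * sqrt((n - 2) / pmax(1 - r^2,
                                                  .Machine$double.xmin))),
                     n - 2))
  pmin(p, 1)
}

#' Build the thresholded bipartite lncRNA-mRNA co-expression network
#'
#' Tests every lncRNA-mRNA pair over all samples of the matrix (cases and
#' controls pooled) and retains pairs with `|r| > rThreshold` and
#' `p < pThreshold`, both strict. Constant-expression genes are skipped with
#' a warning (their correlations are undefined). Node regulation labels
#' (`up`/`down`) are copied from the first DEG table supplied, when any.
#'
#' @param expr a [SummarizedExperiment] as in [runComparison()].
#' @param lncSet,mrnaSet disjoint character vectors of gene ids present in
#'   `expr` (typically the intersected significant lncRNAs and mRNAs from
#'   [intersectComparisons()]).
#' @param degTables optional list of DEG tables used to annotate node
#'   regulation.
#' @param rThreshold,pThreshold retention thresholds (defaults 0.8 and 0.01).
#' @return a [CoexprNetwork-class]; empty (with a warning) when either
#'   candidate set is empty.
#' @examples
#' sim <- simulateBulk(nGenes = 80, nLnc = 8, hubDegree = 6, seed = 1)
#' deg <- runComparison(sim$expr, "IPF", "normal")
#' ipf <- intersectComparisons(list(deg))
#' net <- buildNetwork(sim$expr, ipf$lnc, ipf$mrna, list(deg))
#' net
#' @export
buildNetwork <- function(expr, lncSet, mrnaSet, degTables = NULL,
                         rThreshold = 0.8, pThreshold = 0.01) {
  mat <- assay(expr, 1L)
  if (length(intersect(lncSet, mrnaSet)))
    stop("'lncSet' and 'mrnaSet' must be disjoint")
  if (!all(c(lncSet, mrnaSet) %in% rownames(mat)))
    stop("candidate genes missing from the expression matrix")
  emptyNet <- function() {
    warning("empty candidate set: returning an empty network")
    new("CoexprNetwork",
        edges = S4Vectors::DataFrame(lnc = character(), mrna = character(),
                                     r = numeric(), p = numeric(),
                                     sign = character()),
        nodes = S4Vectors::DataFrame(id = character(), biotype = character(),
                                     regulation = character(),
                                     degree = integer()),
        thresholds = list(r = rThreshold, p = pThreshold))
  }
  if (!length(lncSet) || !length(mrnaSet)) return(emptyNet())
  constant <- rownames(mat)[apply(mat, 1L, sd) == 0]
  if (length(intersect(constant, c(lncSet, mrnaSet)))) {
    warning("skipping constant-expression genes: ",
            paste(intersect(constant, c(lncSet, mrnaSet)), collapse = ", "))
    lncSet <- setdiff(lncSet, constant)
    mrnaSet <- setdiff(mrnaSet, constant)
    if (!length(lncSet) || !length(mrnaSet)) return(emptyNet())
  }
  n <- ncol(mat)
  rmat <- cor(t(mat[lncSet, , drop = FALSE]),
              t(mat[mrnaSet, , drop = FALSE]))
  pmat <- corPValue(rmat, n)
  keep <- which(abs(rmat) > rThreshold & pmat < pThreshold, arr.ind = TRUE)
  edges <- S4Vectors::DataFrame(
    lnc = lncSet[keep[, 1L]],
    mrna = mrnaSet[keep[, 2L]],
    r = rmat[keep],
    p = pmat[keep],
    sign = ifelse(rmat[keep] > 0, "positive", "negative"))
  edges <- edges[order(edges$lnc, edges$mrna), , drop = FALSE]

  regulation <- character()
  if (length(degTables))
    regulation <- setNames(degTables[[1]]$direction, degTables[[1]]$gene)
  ids <- sort(unique(c(edges$lnc, edges$mrna)))
  deg <- table(factor(c(edges$lnc, edges$mrna), levels = ids))
  nodes <- S4Vectors::DataFrame(
    id = ids,
    biotype = ifelse(ids %in% lncSet, "lncRNA", "mRNA"),
    regulation = ifelse(ids %in% names(regulation),
                        unname(regulation[ids]), NA_character_),
    degree = as.integer(deg[ids]))
  net <- new("CoexprNetwork", edges = edges, nodes = nodes,
             thresholds = list(r = rThreshold, p = pThreshold))
  validObject(net)
  net
}

#' Degree table of a co-expression network
#'
#' Nodes ordered by decreasing degree (ties broken lexicographically by id),
#' filtered to `degree > minDegreeShown` — the convention used when plotting
#' degree distributions that show only genes above a degree cutoff.
#'
#' @param net a [CoexprNetwork-class].
#' @param minDegreeShown strict lower cutoff (default 0, i.e. all stored
#'   nodes).
#' @return a [S4Vectors::DataFrame] with `node`, `biotype`, `degree`.
#' @export
setMethod("degreeTable", "CoexprNetwork", function(net, minDegreeShown = 0L) {
  nd <- net@nodes
  nd <- nd[nd$degree > minDegreeShown, , drop = FALSE]
  nd <- nd[order(-nd$degree, nd$id), , drop = FALSE]
  S4Vectors::DataFrame(node = nd$id, biotype = nd$biotype, degree = nd$degree)
})

#' Hub gene(s) of a co-expression network
#'
#' The maximum-degree node(s) over the whole network (or within one
#' biotype). Ties are all returned rather than broken arbitrarily.
#'
#' @param net a [CoexprNetwork-class].
#' @param biotype optional `"lncRNA"` or `"mRNA"` to restrict the ranking.
#' @return character vector of node ids (length > 1 only on ties; empty for
#'   an empty network).
#' @export
setMethod("hubGenes", "CoexprNetwork", function(net, biotype = NULL) {
  nd <- net@nodes
  if (!is.null(biotype)) nd <- nd[nd$biotype == biotype, , drop = FALSE]
  if (!nrow(nd)) return(character())
  sort(nd$id[nd$degree == max(nd$degree)])
})

#' Hub-centered subnetwork
#'
#' The induced subgraph on a focal node and its direct neighbors: all edges
#' of the network whose endpoints both lie in that neighborhood. For a
#' bipartite lncRNA-mRNA network this keeps the focal node's incident edges
#' plus any edges between its neighbors and other neighborhood members
#' present in the original edge set.
#'
#' @param net a [CoexprNetwork-class].
#' @param focal a node id present in the network.
#' @return a [CoexprNetwork-class].
#' @export
setMethod("hubSubnetwork", "CoexprNetwork", function(net, focal) {
  nd <- net@nodes
  if (!(focal %in% nd$id))
    stop(sprintf("focal gene '%s' is not in the network", focal))
  ed <- net@edges
  nbrs <- union(ed$mrna[ed$lnc == focal], ed$lnc[ed$mrna == focal])
  keepNodes <- c(focal, nbrs)
  ed2 <- ed[ed$lnc %in% keepNodes & ed$mrna %in% keepNodes, , drop = FALSE]
  ids <- sort(unique(c(ed2$lnc, ed2$mrna)))
  deg <- table(factor(c(ed2$lnc, ed2$mrna), levels = ids))
  nodes <- nd[match(ids, nd$id), , drop = FALSE]
  nodes$degree <- as.integer(deg[ids])
  sub <- new("CoexprNetwork", edges = ed2, nodes = nodes,
             thresholds = net@thresholds)
  validObject(sub)
  sub
})
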