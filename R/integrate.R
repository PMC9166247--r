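#' Merge co-expression, PPI and TF-target layers around a focal gene
#'
#' Builds a typed multi-layer network: co-expression edges (split into
#' `coexpr_pos` / `coexpr_neg`), undirected protein-protein interactions
#' (`ppi`) and directed transcription-factor regulation (`tf_target`).
#' Undirected edges are canonicalized (endpoints sorted) and duplicate
#' `(source, target, edge_type)` triples are removed, so the merge is
#' idempotent and independent of layer order; a pair present in two layers
#' keeps one edge per type. The union is then restricted to the connected
#' neighborhood of the focal gene: nodes within `hops` steps (traversing any
#' edge, ignoring direction) and all retained edges with both endpoints in
#' that ball.
#'
#' @param coexpr a [CoexprNetwork-class], or `NULL`.
#' @param ppiEdges data.frame with >= 2 columns (source, target, optional
#'   provenance), or `NULL`.
#' @param tfEdges data.frame with >= 2 columns (TF, target, optional
#'   provenance), or `NULL`; direction is preserved.
#' @param focal gene id; must appear in at least one layer.
#' @param hops neighborhood radius (default 1, direct interactors).
#' @return data.frame with columns `source`, `target`, `edge_type`,
#'   `directed`, `provenance`; per-layer retained edge counts are in
#'   `attr(, "layer_counts")`.
#' @examples
#' ppi <- data.frame(source = "M1", target = "M3")
#' tf  <- data.frame(source = "TF1", target = "M2")
#' @export
mergeNetworks <- function(coexpr = NULL, ppiEdges = NULL, tfEdges = NULL,
                          focal, hops = 1) {
  layers <- list()
  if (!is.null(coexpr)) {
    stopifnot(is(coexpr, "CoexprNetwork"))
    ed <- netEdges(coexpr)
    if (nrow(ed))
      layers[[length(layers) + 1L]] <- data.frame(
        source = ed$lnc, target = ed$mrna,
        edge_type = ifelse(ed$sign == "positive", "coexpr_pos", "coexpr_neg"),
        directed = FALSE, provenance = "coexpr")
  }
  asLayer <- function(df, type, directed) {
    if (is.null(df) || !nrow(df)) return(NULL)
    if (ncol(df) < 2) stop("edge list needs at least 2 columns")
    data.frame(source = as.character(df[[1]]), target = as.character(df[[2]]),
               edge_type = type, directed = directed,
               provenance = if (ncol(df) >= 3) as.character(df[[3]]) else type)
  }
  layers <- c(layers, list(asLayer(ppiEdges, "ppi", FALSE),
                           asLayer(tfEdges, "tf_target", TRUE)))
  edges <- do.call(rbind, layers)
  if (is.null(edges) || !nrow(edges)) stop("no edges in any layer")
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  # canonical endpoint order for undirected edge types
  swap <- !edges$directed & edges$source > edges$target
  tmp <- edges$source[swap]
  edges$source[swap] <- edges$target[swap]
  edges$target[swap] <- tmp
  edges <- edges[!duplicated(edges[, c("source", "target", "edge_type")]), ,
                 drop = FALSE]
  nodes <- unique(c(edges$source, edges$target))
  if (!(focal %in% nodes))
    stop(sprintf("focal gene '%s' absent from all layers", focal))
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = nodes)
  d <- igraph::distances(g, v = focal)[1L, ]
  keep <- names(d)[is.finite(d) & d <= hops]
  edges <- edges[edges$source %in% keep & edges$target %in% keep, ,
                 drop = FALSE]
  edges <- edges[order(edges$edge_type, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  counts <- table(factor(edges$edge_type,
                         levels = c("coexpr_pos", "coexpr_neg", "ppi",
                                    "tf_target")))
  attr(edges, "layer_counts") <- setNames(as.integer(counts), names(counts))
  edges
}
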