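#' Construct a GeneSetCollection
#'
#' Drops excluded set ids (e.g. disease-specific pathways), intersects every
#' set with the background universe, and drops (with a message) sets left
#' empty.
#'
#' @param sets named list of character vectors (set id -> member genes), e.g.
#'   from [readGMT()] or [simulateGeneSets()].
#' @param universe character vector of background gene ids; a common choice
#'   is all genes of the collapsed expression matrix.
#' @param excludedIds set ids to remove before testing (allow/deny filtering,
#'   e.g. restriction to KEGG top categories, is expressed through this and
#'   through pre-subsetting `sets`).
#' @return a [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets, universe, excludedIds = character()) {
  if (!length(sets)) stop("'sets' must contain at least one gene set")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list")
  sets <- sets[!(names(sets) %in% excludedIds)]
  sets <- lapply(sets, function(s) unique(intersect(s, universe)))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    message("dropping ", sum(empty), " set(s) empty after intersection ",
            "with the universe: ",
            paste(utils::head(names(sets)[empty], 5), collapse = ", "))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no gene sets left after filtering")
  obj <- new("GeneSetCollection", sets = sets,
             universe = unique(universe),
             excludedIds = as.character(excludedIds))
  validObject(obj)
  obj
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT dialect: set name, description, then member
#' genes. Trailing tabs (empty member fields) are tolerated.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character member vectors.
#' @export
readGMT <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, function(s) unique(s[nzchar(s)]))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` annotated genes when drawing `n` genes from a
#' universe of `N` containing `K` annotated ones. Computed through the
#' log-space distribution function, so it is numerically stable for large
#' counts.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K set size in the universe.
#' @param n query size in the universe.
#' @param N universe size.
#' @return the upper-tail probability in (0, 1].
#' @examples
#' hypergeomUpper(3, 4, 5, 10)  # 66/252
#' @importFrom stats phyper
#' @export
hypergeomUpper <- function(k, K, n, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop("inconsistent hypergeometric counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the output keeps the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @importFrom stats p.adjust
#' @export
bhAdjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be finite numbers in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' Tests every set of the collection for over-representation in the query
#' using the upper-tail hypergeometric model, adjusts p-values by the
#' Benjamini-Hochberg procedure, and flags sets with FDR below the
#' threshold. Query genes outside the universe are dropped with a message.
#'
#' @param query character vector of gene ids (e.g. the mRNAs correlated with
#'   a hub lncRNA); its intersection with the universe must be non-empty.
#' @param collection a [GeneSetCollection-class].
#' @param fdrThreshold significance cutoff on the adjusted p (default 0.05).
#' @return [S4Vectors::DataFrame] sorted by ascending p, one row per set:
#'   `set_id`, `k` (overlap), `K` (set size), `n` (query size), `N`
#'   (universe size), `p_hyper`, `fdr`, `significant`.
#' @export
enrichGeneSets <- function(query, collection, fdrThreshold = 0.05) {
  stopifnot(is(collection, "GeneSetCollection"))
  uni <- collection@universe
  dropped <- setdiff(query, uni)
  query <- unique(intersect(query, uni))
  if (!length(query))
    stop("query has no genes in the universe")
  if (length(dropped))
    message(length(dropped), " query gene(s) outside the universe dropped")
  N <- length(uni)
  n <- length(query)
  K <- lengths(collection@sets)
  k <- vapply(collection@sets, function(s) length(intersect(s, query)),
              integer(1))
  p <- hypergeomUpper(k, K, n, N)
  fdr <- bhAdjust(p)
  out <- S4Vectors::DataFrame(
    set_id = names(collection@sets), k = unname(k), K = unname(K),
    n = n, N = N,
    p_hyper = unname(p), fdr = unname(fdr),
    significant = unname(fdr < fdrThreshold))
  rownames(out) <- NULL
  out[order(out$p_hyper, out$set_id), , drop = FALSE]
}

#' Gene-to-gene-set crosstalk links
#'
#' One row per (gene, set) membership pair among a focal gene's correlated
#' partners — the link table behind a Sankey diagram connecting hub-partner
#' mRNAs to curated fibrosis gene sets.
#'
#' @param genes character vector (e.g. the hub's neighbor mRNAs).
#' @param collection a [GeneSetCollection-class].
#' @return data.frame with columns `gene` (source) and `set_id` (target);
#'   empty when there are no memberships.
#' @export
crosstalkTable <- function(genes, collection) {
  stopifnot(is(collection, "GeneSetCollection"))
  links <- lapply(names(collection@sets), function(id) {
    hit <- intersect(genes, collection@sets[[id]])
    if (length(hit)) data.frame(gene = hit, set_id = id) else NULL
  })
  out <- do.call(rbind, links)
  if (is.null(out)) out <- data.frame(gene = character(),
                                      set_id = character())
  out[order(out$gene, out$set_id), , drop = FALSE]
}
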