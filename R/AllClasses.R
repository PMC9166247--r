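#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CoexprNetwork: a thresholded bipartite lncRNA-mRNA co-expression network
#'
#' Holds the edges retained at the correlation and p-value thresholds
#' (|r| > rThreshold, p < pThreshold, both strict) together with node
#' attributes. The graph is bipartite by construction: every edge joins a
#' lncRNA to an mRNA. Nodes are stored only while incident to at least one
#' edge, so the minimum degree is 1.
#'
#' @slot edges [S4Vectors::DataFrame] with columns `lnc`, `mrna`, `r`, `p`,
#'   `sign` (`"positive"`/`"negative"`, the sign of r).
#' @slot nodes [S4Vectors::DataFrame] with columns `id`, `biotype`
#'   (`"lncRNA"`/`"mRNA"`), `regulation` (`"up"`/`"down"`/`NA`) and `degree`.
#' @slot thresholds named list with `r` and `p`, the thresholds used.
#'
#' @seealso [buildNetwork()], [degreeTable()], [hubGenes()], [hubSubnetwork()]
#' @export
setClass("CoexprNetwork",
  slots = c(edges = "DataFrame", nodes = "DataFrame", thresholds = "list"))

setValidity("CoexprNetwork", function(object) {
  ed <- object@edges
  nd <- object@nodes
  msgs <- character()
  need_e <- c("lnc", "mrna", "r", "p", "sign")
  need_n <- c("id", "biotype", "regulation", "degree")
  if (!all(need_e %in% colnames(ed)))
    return(paste("edges must have columns", paste(need_e, collapse = ", ")))
  if (!all(need_n %in% colnames(nd)))
    return(paste("nodes must have columns", paste(need_n, collapse = ", ")))
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "duplicate node ids")
  if (nrow(ed) > 0) {
    bt <- setNames(nd$biotype, nd$id)
    if (!all(ed$lnc %in% nd$id) || !all(ed$mrna %in% nd$id))
      msgs <- c(msgs, "edge endpoint missing from node table")
    else if (!all(bt[ed$lnc] == "lncRNA") || !all(bt[ed$mrna] == "mRNA"))
      msgs <- c(msgs, "network is not bipartite lncRNA-mRNA")
    if (!all((ed$sign == "positive") == (ed$r > 0)))
      msgs <- c(msgs, "edge sign inconsistent with r")
  }
  # degree bookkeeping: recomputed degrees must match, no isolated nodes
  deg <- table(factor(c(ed$lnc, ed$mrna), levels = nd$id))
  if (nrow(nd) > 0 && !all(as.integer(deg[nd$id]) == nd$degree))
    msgs <- c(msgs, "stored degrees do not match edge list")
  if (nrow(nd) > 0 && any(nd$degree < 1L))
    msgs <- c(msgs, "isolated nodes are not stored")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn CoexprNetwork-class number of edges
#' @param x,object a `CoexprNetwork`
#' @export
setMethod("length", "CoexprNetwork", function(x) nrow(x@edges))

setMethod("show", "CoexprNetwork", function(object) {
  nd <- object@nodes
  cat("CoexprNetwork:",
      sum(nd$biotype == "lncRNA"), "lncRNAs,",
      sum(nd$biotype == "mRNA"), "mRNAs,",
      nrow(object@edges), "edges\n")
  cat("  thresholds: |r| >", object@thresholds$r,
      ", p <", object@thresholds$p, "\n")
  if (nrow(nd) > 0) {
    top <- nd[order(-nd$degree, nd$id), , drop = FALSE][1L, ]
    cat("  top-degree node:", top$id, "(degree", paste0(top$degree, ")"), "\n")
  }
})

#' BulkTruth: planted structure of a simulated bulk expression matrix
#'
#' Records what [simulateBulk()] planted, so downstream stages can be scored
#' against ground truth: the up- and down-regulated gene sets, and for each
#' planted hub lncRNA the set of partner mRNAs sharing its latent factor.
#'
#' @slot deUp,deDown character vectors of planted up-/down-regulated gene ids
#'   (disjoint).
#' @slot hubLncs named list: hub lncRNA id -> character vector of partner
#'   mRNA ids. Hubs and partners are all planted differentially expressed, so
#'   they survive the DEG filter and enter the network.
#' @slot effectSize,rhoTarget,sigma numeric generator parameters (log2-scale
#'   shift, within-group latent correlation, residual sd).
#' @slot seed integer seed used.
#' @export
setClass("BulkTruth",
  slots = c(deUp = "character", deDown = "character", hubLncs = "list",
            effectSize = "numeric", rhoTarget = "numeric", sigma = "numeric",
            seed = "integer"))

setValidity("BulkTruth", function(object) {
  if (length(intersect(object@deUp, object@deDown)) > 0)
    return("deUp and deDown overlap")
  de <- union(object@deUp, object@deDown)
  partners <- unlist(object@hubLncs, use.names = FALSE)
  if (!all(partners %in% de))
    return("hub partners must be planted differentially expressed")
  if (!all(names(object@hubLncs) %in% de))
    return("hub lncRNAs must be planted differentially expressed")
  TRUE
})

setMethod("show", "BulkTruth", function(object) {
  cat("BulkTruth:", length(object@deUp), "up,", length(object@deDown),
      "down planted DE genes;", length(object@hubLncs), "hub lncRNA(s)\n")
  for (h in names(object@hubLncs))
    cat("  ", h, ": ", length(object@hubLncs[[h]]), " partner mRNAs\n", sep = "")
})

#' SCTruth: planted structure of a simulated single-cell dataset
#'
#' @slot lowQualityCells named character vector: cell id -> reason, one of
#'   `few_genes`, `many_genes`, `high_mito`. Each planted cell violates the
#'   generator's threshold for its reason by construction.
#' @slot rareGenes character vector of genes planted detected in fewer cells
#'   than the min-cells threshold (they fail the gene filter).
#' @slot thresholds named list of the QC thresholds the dataset was built
#'   against (`minGenes`, `minCells`, `maxGenes`, `maxMito`).
#' @slot seed integer seed used.
#' @export
setClass("SCTruth",
  slots = c(lowQualityCells = "character", rareGenes = "character",
            thresholds = "list", seed = "integer"))

setValidity("SCTruth", function(object) {
  ok <- c("few_genes", "many_genes", "high_mito")
  if (length(object@lowQualityCells) &&
      !all(object@lowQualityCells %in% ok))
    return(paste("low-quality reasons must be one of",
                 paste(ok, collapse = ", ")))
  TRUE
})

setMethod("show", "SCTruth", function(object) {
  tab <- table(object@lowQualityCells)
  cat("SCTruth:", length(object@lowQualityCells), "planted low-quality cells")
  if (length(tab)) cat(" (", paste(names(tab), as.integer(tab), sep = ":",
                                   collapse = ", "), ")", sep = "")
  cat(";", length(object@rareGenes), "rare genes\n")
})

#' QCReport: per-step accounting of the single-cell QC cascade
#'
#' Mirrors the reporting style of the filter narrative: cells failing the
#' min-genes cutoff, then genes detected in too few cells, then cells with too
#' many genes or an excessive mitochondrial UMI fraction. The accounting
#' identities `nCellsOut = nCellsIn - removedCellsMinGenes -
#' removedCellsMaxGenesOrMito` and `nGenesOut = nGenesIn -
#' removedGenesMinCells` are enforced by the validity method.
#'
#' @slot nCellsIn,nGenesIn,nCellsOut,nGenesOut integer dimensions.
#' @slot removedCellsMinGenes,removedGenesMinCells,removedCellsMaxGenesOrMito
#'   integer per-step removal counts.
#' @slot thresholds named list of thresholds used.
#' @export
setClass("QCReport",
  slots = c(nCellsIn = "integer", nGenesIn = "integer",
            removedCellsMinGenes = "integer", removedGenesMinCells = "integer",
            removedCellsMaxGenesOrMito = "integer",
            nCellsOut = "integer", nGenesOut = "integer",
            thresholds = "list"))

setValidity("QCReport", function(object) {
  if (object@nCellsOut != object@nCellsIn - object@removedCellsMinGenes -
      object@removedCellsMaxGenesOrMito)
    return("cell accounting identity violated")
  if (object@nGenesOut != object@nGenesIn - object@removedGenesMinCells)
    return("gene accounting identity violated")
  TRUE
})

setMethod("show", "QCReport", function(object) {
  th <- object@thresholds
  cat("QCReport (", object@nCellsIn, " cells x ", object@nGenesIn,
      " genes in)\n", sep = "")
  cat("  1. removed", object@removedCellsMinGenes, "cells with <",
      th$minGenes, "detected genes\n")
  cat("  2. removed", object@removedGenesMinCells, "genes detected in <",
      th$minCells, "cells\n")
  cat("  3. removed", object@removedCellsMaxGenesOrMito, "cells with >",
      th$maxGenes, "genes or >", th$maxMito, "mito fraction\n")
  cat("  ->", object@nCellsOut, "cells x", object@nGenesOut, "genes out\n")
})

#' GeneSetCollection: curated gene sets over a background universe
#'
#' A named list of member-gene vectors together with the background universe
#' used for enrichment. Disease-specific (or otherwise excluded) set ids are
#' dropped at construction; members outside the universe are trimmed; sets
#' left empty are dropped with a message.
#'
#' @slot sets named list of character vectors (members, already intersected
#'   with the universe; all non-empty).
#' @slot universe character vector of background gene ids.
#' @slot excludedIds character vector of set ids removed at construction.
#' @export
setClass("GeneSetCollection",
  slots = c(sets = "list", universe = "character", excludedIds = "character"))

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      return("sets must be uniquely named")
    if (any(lengths(object@sets) == 0))
      return("empty gene set after intersecting with universe")
    if (!all(unlist(object@sets, use.names = FALSE) %in% object@universe))
      return("set members outside the universe")
    if (any(names(object@sets) %in% object@excludedIds))
      return("excluded set ids must not be stored")
  }
  TRUE
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets over a universe of",
      length(object@universe), "genes")
  if (length(object@excludedIds))
    cat(" (", length(object@excludedIds), " excluded)", sep = "")
  cat("\n")
})
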