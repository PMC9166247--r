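#' @rdname CoexprNetwork-class
#' @export
setGeneric("netEdges", function(x) standardGeneric("netEdges"))

#' @rdname CoexprNetwork-class
#' @export
setGeneric("netNodes", function(x) standardGeneric("netNodes"))

#' @rdname degreeTable
#' @export
setGeneric("degreeTable",
  function(net, minDegreeShown = 0L) standardGeneric("degreeTable"))

#' @rdname hubGenes
#' @export
setGeneric("hubGenes",
  function(net, biotype = NULL) standardGeneric("hubGenes"))

#' @rdname hubSubnetwork
#' @export
setGeneric("hubSubnetwork",
  function(net, focal) standardGeneric("hubSubnetwork"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname CoexprNetwork-class
#' @export
setMethod("netEdges", "CoexprNetwork", function(x) x@edges)

#' @rdname CoexprNetwork-class
#' @export
setMethod("netNodes", "CoexprNetwork", function(x) x@nodes)

#' @rdname GeneSetCollection-class
#' @param x a `GeneSetCollection`
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneUniverse", "GeneSetCollection", function(x) x@universe)
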