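#' @rdname ProteinNetwork-class
#' @param x a ProteinNetwork
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname ProteinNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname GeneSets-class
#' @param x a GeneSets
#' @export
setGeneric("degGenes", function(x) standardGeneric("degGenes"))

#' @rdname GeneSets-class
#' @export
setGeneric("backgroundGenes", function(x) standardGeneric("backgroundGenes"))

#' @rdname GeneSets-class
#' @export
setGeneric("geneMapping", function(x) standardGeneric("geneMapping"))

#' @rdname LabeledGraph-class
#' @param x a LabeledGraph
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' @rdname LabeledGraph-class
#' @param u,v vertex identifiers
#' @export
setGeneric("edgeWeight", function(x, u, v) standardGeneric("edgeWeight"))

#' @rdname CliqueCollection-class
#' @param x a CliqueCollection
#' @export
setGeneric("uniqueCliques", function(x) standardGeneric("uniqueCliques"))

#' @rdname CliqueCollection-class
#' @export
setGeneric("cliqueMultiplicity",
           function(x) standardGeneric("cliqueMultiplicity"))

#' @rdname RegulatoryModule-class
#' @param x a RegulatoryModule
#' @export
setGeneric("moduleNodes", function(x) standardGeneric("moduleNodes"))

#' @rdname RegulatoryModule-class
#' @export
setGeneric("moduleEdges", function(x) standardGeneric("moduleEdges"))

#' @rdname RegulatoryModule-class
#' @export
setGeneric("moduleAnnotations",
           function(x) standardGeneric("moduleAnnotations"))

#' @rdname RegulatoryModule-class
#' @export
setGeneric("submodules", function(x) standardGeneric("submodules"))

#' Connected components of a regulatory module
#'
#' @param x a [RegulatoryModule-class]
#' @return named integer vector assigning each module node to a
#'   connected component (empty for an empty module).
#' @export
setGeneric("connectedComponents",
           function(x) standardGeneric("connectedComponents"))

#' @rdname StabilityReport-class
#' @param x a StabilityReport
#' @export
setGeneric("variability", function(x) standardGeneric("variability"))

#' @rdname StabilityReport-class
#' @export
setGeneric("pairwiseDistances",
           function(x) standardGeneric("pairwiseDistances"))
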