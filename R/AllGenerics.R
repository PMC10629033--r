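#' @rdname MultilayerNetwork-class
#' @param x a \code{MultilayerNetwork} (or \code{FlatGraph} where sensible)
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname MultilayerNetwork-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname MultilayerNetwork-class
#' @export
setGeneric("layerIds", function(x) standardGeneric("layerIds"))

#' @rdname MultilayerNetwork-class
#' @export
setGeneric("interlayerId", function(x) standardGeneric("interlayerId"))

#' @rdname MultilayerNetwork-class
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname MultilayerNetwork-class
#' @export
setGeneric("intralayerEdges", function(x) standardGeneric("intralayerEdges"))

#' @rdname MultilayerNetwork-class
#' @export
setGeneric("interlayerEdges", function(x) standardGeneric("interlayerEdges"))

#' Neighbors of a node across all layers
#'
#' The neighborhood used throughout the package (Jaccard refinement in
#' particular) is the union of a node's partners over intralayer and
#' interlayer edges alike: a node is characterized by the whole set of its
#' interactions, regardless of the layer they live on.
#'
#' @param x a [MultilayerNetwork-class]
#' @param node a node identifier present in the network
#' @return character vector of neighboring node identifiers (sorted)
#' @export
setGeneric("nodeNeighbors", function(x, node) standardGeneric("nodeNeighbors"))

#' @rdname toFlat
#' @export
setGeneric("toFlat", function(x) standardGeneric("toFlat"))

#' @rdname toFlat
#' @export
setGeneric("fromFlat", function(x) standardGeneric("fromFlat"))

#' @rdname Alignment-class
#' @param x an \code{Alignment}
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))

#' @rdname Alignment-class
#' @export
setGeneric("permutationsUsed", function(x) standardGeneric("permutationsUsed"))

#' @rdname SimilarityMatrix-class
#' @param x a \code{SimilarityMatrix} or \code{NodeEmbeddings}
#' @export
setGeneric("values", function(x) standardGeneric("values"))
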