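#' @import methods
NULL

.emptyEdges <- function() {
  data.frame(u = character(0), v = character(0), layer = integer(0),
             stringsAsFactors = FALSE)
}

#' MultilayerNetwork: an attributed edge-list multilayer network
#'
#' The central container of the package. A multilayer network is stored as a
#' set of undirected edges \code{(u, v, layer)}: intralayer edges carry the
#' identifier of their layer, interlayer edges carry a dedicated identifier.
#' Edges are canonicalized (\code{u < v} lexicographically) and stored once;
#' self-loops are rejected. The node set is the set of edge endpoints, so a
#' valid network never contains an isolated node.
#'
#' @slot edges data.frame with character columns \code{u}, \code{v} and
#'   integer column \code{layer}.
#' @slot layerIds integer vector of intralayer identifiers, in layer order.
#' @slot interlayerId integer identifier tagging interlayer edges
#'   (\code{NA} when the network declares no interlayer).
#' @seealso [multilayerNetwork()], [readEdgeList()], [toFlat()]
#' @exportClass MultilayerNetwork
setClass("MultilayerNetwork",
  representation(edges = "data.frame", layerIds = "integer",
                 interlayerId = "integer"),
  prototype(edges = .emptyEdges(), layerIds = integer(0),
            interlayerId = NA_integer_))

setValidity("MultilayerNetwork", function(object) {
  e <- object@edges
  msgs <- character(0)
  if (!identical(names(e), c("u", "v", "layer")))
    return("edges must have columns u, v, layer")
  if (!is.character(e$u) || !is.character(e$v) || !is.integer(e$layer))
    return("edge columns must be character, character, integer")
  if (any(e$u == e$v))
    msgs <- c(msgs, "self-loops are not allowed")
  if (any(e$u > e$v))
    msgs <- c(msgs, "edges must be stored in canonical order (u < v)")
  if (anyDuplicated(e))
    msgs <- c(msgs, "duplicate edges are not allowed")
  known <- c(object@layerIds, object@interlayerId)
  if (nrow(e) && !all(e$layer %in% known[!is.na(known)]))
    msgs <- c(msgs, "every edge layer must be a declared layer id or the interlayer id")
  if (!is.na(object@interlayerId) && object@interlayerId %in% object@layerIds)
    msgs <- c(msgs, "interlayer id must differ from the intralayer ids")
  if (length(msgs)) msgs else TRUE
})

#' FlatGraph: the typed-edge flat representation of a multilayer network
#'
#' A single graph whose edges are typed by the originating layer identifier.
#' The flat representation is lossless: [fromFlat()] reconstructs the
#' original [MultilayerNetwork-class].
#'
#' @slot edges data.frame with columns \code{u}, \code{v}, \code{type}.
#' @slot layerIds,interlayerId layer bookkeeping carried along so the
#'   multilayer form can be reconstructed.
#' @exportClass FlatGraph
setClass("FlatGraph",
  representation(edges = "data.frame", layerIds = "integer",
                 interlayerId = "integer"))

#' NodeEmbeddings: per-node vectors learned from random-walk corpora
#'
#' @slot vectors numeric matrix, one row per node (rownames are node
#'   identifiers), \code{dimensions} columns.
#' @slot config the embedding configuration used (see [embeddingConfig()]).
#' @exportClass NodeEmbeddings
setClass("NodeEmbeddings",
  representation(vectors = "matrix", config = "list"))

setValidity("NodeEmbeddings", function(object) {
  if (is.null(rownames(object@vectors)))
    return("embedding matrix must carry node identifiers as rownames")
  if (anyDuplicated(rownames(object@vectors)))
    return("duplicate node identifiers in embedding matrix")
  TRUE
})

#' SimilarityMatrix: source-by-target node similarity
#'
#' Rows are source-network nodes, columns target-network nodes. Built from
#' embeddings ([buildSimilarityMatrix()]) or read from a labelled file
#' ([readSimilarityMatrix()]).
#'
#' @slot values numeric matrix with row/column names.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("similarity values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("similarity matrix must carry source/target labels as dimnames")
  if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
    return("duplicate node labels in similarity matrix")
  if (any(!is.finite(v))) return("similarity values must be finite")
  TRUE
})

#' Alignment: a one-to-one node mapping between two networks
#'
#' @slot pairs data.frame with columns \code{source}, \code{target},
#'   \code{score} (and, after refinement, \code{jaccard}).
#' @slot permutationsUsed number of accepted swaps during refinement.
#' @slot stopReason why refinement stopped (\code{"converged"},
#'   \code{"all_overlapped"}, \code{"budget_exhausted"} or \code{"none"}).
#' @exportClass Alignment
setClass("Alignment",
  representation(pairs = "data.frame", permutationsUsed = "integer",
                 stopReason = "character"),
  prototype(permutationsUsed = 0L, stopReason = "none"))

setValidity("Alignment", function(object) {
  p <- object@pairs
  if (!all(c("source", "target", "score") %in% names(p)))
    return("pairs must have columns source, target, score")
  if (anyDuplicated(p$source) || anyDuplicated(p$target))
    return("alignment must be one-to-one")
  TRUE
})

#' EvaluationReport: KPI summary for one alignment
#'
#' @slot nc node correctness.
#' @slot counts named integer vector (tp, fp, tn, fn) at the full-mapping
#'   operating point (tn = 0 there by construction; see the vignette).
#' @slot tpr,fpr true/false positive rate at that operating point.
#' @slot auc area under the score-threshold ROC curve.
#' @slot f1 harmonic mean of precision and recall.
#' @slot mcc Matthews correlation coefficient.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(nc = "numeric", counts = "integer", tpr = "numeric",
                 fpr = "numeric", auc = "numeric", f1 = "numeric",
                 mcc = "numeric"))
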