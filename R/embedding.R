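#' Embedding configuration
#'
#' Hyperparameters of the random-walk + skip-gram node embedding. Defaults
#' are the customary node2vec settings: 128-dimensional vectors, 10 walks of
#' 80 steps per node, window 5, 5 training epochs, unbiased second-order
#' walks (\code{returnParam = inoutParam = 1}). Training is single-threaded
#' and deterministic under a fixed seed; initial vectors are derived from
#' each node identifier's hash combined with the seed, so networks sharing
#' identifiers are embedded in a common coordinate frame (this is what makes
#' cosine similarity across two independently trained embeddings
#' meaningful).
#'
#' @param dimensions hidden-layer size N (vector length)
#' @param numWalks walks started per node
#' @param walkLength nodes per walk
#' @param window rolling-window radius w: contexts at distance up to w
#' @param epochs training passes over the walk corpus
#' @param seed RNG seed for walks, initialization and training
#' @param returnParam,inoutParam second-order walk bias parameters; values
#'   above 1 discourage backtracking / outward moves respectively
#' @param negative negative samples per positive context
#' @param alpha initial learning rate (linearly decayed)
#' @return a validated list of class \code{EmbeddingConfig}
#' @export
embeddingConfig <- function(dimensions = 128, numWalks = 10, walkLength = 80,
                            window = 5, epochs = 5, seed = 1L,
                            returnParam = 1, inoutParam = 1,
                            negative = 5, alpha = 0.025) {
  stopifnot(dimensions >= 1, numWalks >= 1, walkLength >= 1, window >= 1,
            epochs >= 1, negative >= 0, alpha > 0,
            returnParam > 0, inoutParam > 0)
  structure(list(dimensions = as.integer(dimensions),
                 numWalks = as.integer(numWalks),
                 walkLength = as.integer(walkLength),
                 window = as.integer(window), epochs = as.integer(epochs),
                 seed = as.integer(seed), returnParam = returnParam,
                 inoutParam = inoutParam, negative = as.integer(negative),
                 alpha = alpha),
            class = "EmbeddingConfig")
}

#' Generate second-order biased random walks over a flat graph
#'
#' Starts \code{numWalks} walks of exactly \code{walkLength} nodes from
#' every node. The walk treats the flat graph as untyped and unweighted:
#' intralayer and interlayer edges are traversed alike, so a node's context
#' reflects the whole set of its interactions across all layers.
#'
#' @param g a [FlatGraph-class] (or a [MultilayerNetwork-class], flattened
#'   on the fly)
#' @param config an [embeddingConfig()]
#' @return object of class \code{WalkCorpus}: list with \code{walks} (an
#'   integer matrix, one walk per row) and \code{nodes} (the identifier for
#'   each integer)
#' @export
randomWalks <- function(g, config) {
  stopifnot(inherits(config, "EmbeddingConfig"))
  if (is(g, "MultilayerNetwork")) g <- toFlat(g)
  stopifnot(is(g, "FlatGraph"))
  a <- .adjacency(g)
  if (!length(a$nodes)) stop("cannot walk an empty graph")
  iso <- which(lengths(a$adj) == 0L)
  if (length(iso))
    stop("isolated node(s) cannot be walked: ",
         paste(a$nodes[iso], collapse = ", "))
  walks <- cpp_random_walks(a$adj, config$numWalks, config$walkLength,
                            config$returnParam, config$inoutParam,
                            config$seed)
  structure(list(walks = walks, nodes = a$nodes), class = "WalkCorpus")
}

#' @export
print.WalkCorpus <- function(x, ...) {
  cat("WalkCorpus:", nrow(x$walks), "walks of length", ncol(x$walks),
      "over", length(x$nodes), "nodes\n")
  invisible(x)
}

#' Coerce a walk corpus to a list of node-identifier sequences
#' @param x a \code{WalkCorpus}
#' @export
walkSequences <- function(x) {
  stopifnot(inherits(x, "WalkCorpus"))
  lapply(seq_len(nrow(x$walks)), function(i) x$nodes[x$walks[i, ]])
}

#' Train skip-gram embeddings on a walk corpus
#'
#' A skip-gram model with negative sampling, hidden-layer size
#' \code{dimensions} and window \code{window}, trained single-threaded with
#' the configured seed: the same corpus and seed always yield the identical
#' embedding matrix.
#'
#' @param corpus a \code{WalkCorpus} from [randomWalks()]
#' @param config the [embeddingConfig()] used to produce the corpus
#' @return a [NodeEmbeddings-class]
#' @export
trainEmbeddings <- function(corpus, config) {
  stopifnot(inherits(corpus, "WalkCorpus"),
            inherits(config, "EmbeddingConfig"))
  covered <- sort(unique(as.vector(corpus$walks)))
  missing <- setdiff(seq_along(corpus$nodes), covered)
  if (length(missing))
    stop("corpus does not cover node(s): ",
         paste(corpus$nodes[missing], collapse = ", "))
  init <- cpp_init_vectors(corpus$nodes, config$dimensions,
                           as.double(config$seed))
  m <- cpp_sgns(corpus$walks, length(corpus$nodes), config$dimensions,
                config$window, config$epochs, config$negative,
                config$alpha, as.double(config$seed), init)
  rownames(m) <- corpus$nodes
  new("NodeEmbeddings", vectors = m, config = unclass(config))
}

#' Embed a network end to end
#'
#' Convenience wrapper: flatten, walk, train.
#'
#' @param net a [MultilayerNetwork-class]
#' @param config an [embeddingConfig()]
#' @return a [NodeEmbeddings-class]
#' @export
embedNetwork <- function(net, config = embeddingConfig()) {
  trainEmbeddings(randomWalks(net, config), config)
}

#' Query a node's embedding vector
#'
#' Returns the vector used on the source side of the similarity
#' computation: the node's own projection-weight vector (optionally
#' L2-normalized, which leaves cosine similarity unchanged).
#'
#' @param e a [NodeEmbeddings-class]
#' @param node node identifier
#' @param unitNorm return the L2-normalized vector
#' @return numeric vector of length \code{dimensions}
#' @export
nodeVector <- function(e, node, unitNorm = FALSE) {
  stopifnot(is(e, "NodeEmbeddings"))
  if (!node %in% rownames(e@vectors)) stop("unknown node: ", node)
  v <- e@vectors[node, ]
  if (unitNorm) v <- v / sqrt(sum(v^2))
  v
}

#' @describeIn nodeVector the full embedding matrix
#' @param x a [NodeEmbeddings-class]
#' @export
setMethod("values", "NodeEmbeddings", function(x) x@vectors)

setMethod("show", "NodeEmbeddings", function(object) {
  cat("NodeEmbeddings:", nrow(object@vectors), "nodes x",
      ncol(object@vectors), "dimensions\n")
})

#' Write embeddings in the word2vec text format
#'
#' First line \code{"<count> <dim>"}, then one node and its vector per line.
#'
#' @param e a [NodeEmbeddings-class]
#' @param path output file path
#' @export
writeEmbeddings <- function(e, path) {
  stopifnot(is(e, "NodeEmbeddings"))
  m <- e@vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(rownames(m)[i],
                     paste(formatC(m[i, ], format = "g", digits = 8),
                           collapse = " ")), con)
  invisible(path)
}
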