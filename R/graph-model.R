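#' Construct a MultilayerNetwork from an edge table
#'
#' Edges are undirected: \code{(u, v, l)} and \code{(v, u, l)} denote the
#' same edge and are stored once under canonical ordering. Duplicate edges
#' are collapsed with a warning; self-loops are an error. When
#' \code{layerIds}/\code{interlayerId} are not supplied, the interlayer
#' identifier is inferred as the largest layer identifier present (the
#' conventional numbering assigns increasing integers to the layers and the
#' last one to the interlayer) and the remaining identifiers are the
#' intralayer ids.
#'
#' @param edges data.frame (or coercible) with columns \code{u}, \code{v},
#'   \code{layer}; node identifiers are treated as opaque strings.
#' @param layerIds integer vector of intralayer identifiers, or \code{NULL}
#'   to infer.
#' @param interlayerId integer identifier of interlayer edges, \code{NULL}
#'   to infer, or \code{NA} for a network without interlayer edges.
#' @return a validated [MultilayerNetwork-class]
#' @examples
#' net <- multilayerNetwork(data.frame(u = c("a", "c", "a"),
#'                                     v = c("b", "d", "c"),
#'                                     layer = c(1L, 2L, 3L)))
#' edgeCount(net)          # 3
#' interlayerId(net)       # 3
#' @export
multilayerNetwork <- function(edges, layerIds = NULL, interlayerId = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("u", "v", "layer") %in% names(edges)))
    stop("edges must have columns u, v, layer")
  edges <- edges[, c("u", "v", "layer")]
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  edges$layer <- as.integer(edges$layer)
  if (any(is.na(edges$layer))) stop("layer identifiers must be integers")
  if (any(edges$u == edges$v))
    stop("self-loops are not allowed: ",
         paste(unique(edges$u[edges$u == edges$v]), collapse = ", "))
  flip <- edges$u > edges$v
  if (any(flip)) {
    tmp <- edges$u[flip]
    edges$u[flip] <- edges$v[flip]
    edges$v[flip] <- tmp
  }
  dup <- duplicated(edges)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed")
    edges <- edges[!dup, , drop = FALSE]
  }
  present <- sort(unique(edges$layer))
  if (is.null(interlayerId)) {
    if (is.null(layerIds)) {
      interlayerId <- if (length(present) >= 2L) max(present) else NA_integer_
    } else {
      cand <- setdiff(present, as.integer(layerIds))
      if (length(cand) > 1L)
        stop("cannot infer interlayer id: more than one undeclared layer (",
             paste(cand, collapse = ", "), ")")
      interlayerId <- if (length(cand)) cand else NA_integer_
    }
  }
  interlayerId <- as.integer(interlayerId)
  if (is.null(layerIds))
    layerIds <- setdiff(present, interlayerId)
  layerIds <- as.integer(layerIds)
  unknown <- setdiff(present, c(layerIds, interlayerId))
  if (length(unknown))
    stop("unknown layer id(s): ", paste(unknown, collapse = ", "))
  edges <- edges[order(edges$layer, edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  new("MultilayerNetwork", edges = edges, layerIds = layerIds,
      interlayerId = interlayerId)
}

#' Read a multilayer network from an attributed edge list
#'
#' The dialect is minimal: one edge per line, at least three whitespace- or
#' tab-separated fields \code{u v layer_id} (extra fields ignored),
#' \code{#} comments and blank lines skipped, no header.
#'
#' @param path file path
#' @inheritParams multilayerNetwork
#' @return a [MultilayerNetwork-class]
#' @export
readEdgeList <- function(path, layerIds = NULL, interlayerId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx))
    return(multilayerNetwork(.emptyEdges(),
                             layerIds = layerIds %||% integer(0),
                             interlayerId = interlayerId %||% NA_integer_))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad))
    stop("malformed edge list line ", idx[bad[1]], ": '", lines[idx[bad[1]]],
         "' (need at least 3 fields)")
  lay <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(lay))
    stop("malformed edge list line ", idx[which(is.na(lay))[1]],
         ": non-integer layer id")
  edges <- data.frame(u = vapply(fields, `[`, "", 1L),
                      v = vapply(fields, `[`, "", 2L),
                      layer = lay, stringsAsFactors = FALSE)
  multilayerNetwork(edges, layerIds = layerIds, interlayerId = interlayerId)
}

#' Write a multilayer network as a tab-separated attributed edge list
#'
#' Output round-trips: \code{readEdgeList} of the written file reconstructs
#' an identical network. Edges are emitted in canonical (layer, u, v) order,
#' so identical networks produce byte-identical files.
#'
#' @param net a [MultilayerNetwork-class]
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "MultilayerNetwork"))
  e <- net@edges
  writeLines(sprintf("%s\t%s\t%d", e$u, e$v, e$layer), con = path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn MultilayerNetwork-class sorted node identifiers
#' @export
setMethod("nodeIds", "MultilayerNetwork", function(x)
  sort(unique(c(x@edges$u, x@edges$v))))

#' @describeIn MultilayerNetwork-class the edge table (u, v, layer)
#' @export
setMethod("edgeTable", "MultilayerNetwork", function(x) x@edges)

#' @describeIn MultilayerNetwork-class intralayer identifiers
#' @export
setMethod("layerIds", "MultilayerNetwork", function(x) x@layerIds)

#' @describeIn MultilayerNetwork-class the interlayer identifier
#' @export
setMethod("interlayerId", "MultilayerNetwork", function(x) x@interlayerId)

#' @describeIn MultilayerNetwork-class total number of edges
#' @export
setMethod("edgeCount", "MultilayerNetwork", function(x) nrow(x@edges))

#' @describeIn MultilayerNetwork-class edges whose layer is intralayer
#' @export
setMethod("intralayerEdges", "MultilayerNetwork", function(x)
  x@edges[x@edges$layer %in% x@layerIds, , drop = FALSE])

#' @describeIn MultilayerNetwork-class edges tagged with the interlayer id
#' @export
setMethod("interlayerEdges", "MultilayerNetwork", function(x)
  x@edges[!is.na(x@interlayerId) & x@edges$layer == x@interlayerId, ,
          drop = FALSE])

#' @rdname nodeNeighbors
#' @export
setMethod("nodeNeighbors", "MultilayerNetwork", function(x, node) {
  e <- x@edges
  if (!(node %in% e$u || node %in% e$v))
    stop("unknown node: ", node)
  sort(unique(c(e$v[e$u == node], e$u[e$v == node])))
})

setMethod("show", "MultilayerNetwork", function(object) {
  e <- object@edges
  nIntra <- sum(e$layer %in% object@layerIds)
  cat("MultilayerNetwork with", length(nodeIds(object)), "nodes,",
      nrow(e), "edges\n")
  cat("  layers:", paste(object@layerIds, collapse = ", "),
      "| interlayer id:", object@interlayerId, "\n")
  cat("  intralayer:", nIntra, "| interlayer:", nrow(e) - nIntra, "\n")
})

#' Flat typed-edge representation
#'
#' \code{toFlat} collapses intralayer and interlayer edges into one graph
#' whose edges are typed by the originating layer identifier, keeping the
#' whole topology intact; \code{fromFlat} inverts it without loss.
#'
#' @param x a [MultilayerNetwork-class] (for \code{toFlat}) or a
#'   [FlatGraph-class] (for \code{fromFlat})
#' @return a [FlatGraph-class] or [MultilayerNetwork-class] respectively
#' @name toFlat
NULL

#' @rdname toFlat
#' @export
setMethod("toFlat", "MultilayerNetwork", function(x) {
  e <- x@edges
  names(e)[names(e) == "layer"] <- "type"
  new("FlatGraph", edges = e, layerIds = x@layerIds,
      interlayerId = x@interlayerId)
})

#' @rdname toFlat
#' @export
setMethod("fromFlat", "FlatGraph", function(x) {
  e <- x@edges
  names(e)[names(e) == "type"] <- "layer"
  multilayerNetwork(e, layerIds = x@layerIds, interlayerId = x@interlayerId)
})

#' @describeIn toFlat node identifiers of the flat graph
#' @export
setMethod("nodeIds", "FlatGraph", function(x)
  sort(unique(c(x@edges$u, x@edges$v))))

#' @describeIn toFlat the typed edge table (u, v, type)
#' @export
setMethod("edgeTable", "FlatGraph", function(x) x@edges)

setMethod("show", "FlatGraph", function(object) {
  cat("FlatGraph with", length(nodeIds(object)), "nodes,",
      nrow(object@edges), "typed edges (",
      length(unique(object@edges$type)), "edge types )\n")
})

# Integer adjacency list over the flat (untyped) topology; used by walks and
# by the Jaccard machinery. Returns list(nodes=character, adj=list of int).
.adjacency <- function(net) {
  e <- if (is(net, "FlatGraph")) {
    tmp <- net@edges
    names(tmp)[names(tmp) == "type"] <- "layer"
    tmp
  } else net@edges
  nodes <- sort(unique(c(e$u, e$v)))
  ui <- match(e$u, nodes)
  vi <- match(e$v, nodes)
  adj <- split(c(vi, ui), c(ui, vi))
  out <- rep(list(integer(0)), length(nodes))
  out[as.integer(names(adj))] <- lapply(adj, function(x) sort(unique(x)))
  list(nodes = nodes, adj = out)
}
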