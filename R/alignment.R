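#' Cosine similarity of two vectors
#'
#' @param a,b numeric vectors of equal length, both nonzero
#' @return \code{dot(a, b) / (|a| |b|)}, in \[-1, 1\]
#' @examples
#' cosineSimilarity(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
cosineSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

#' Build the source-by-target cosine similarity matrix
#'
#' Entry \code{[v, u]} is the cosine similarity between the embedding of
#' source node \code{v} and target node \code{u}.
#'
#' @param src,tgt [NodeEmbeddings-class] of the source and target network
#' @return a [SimilarityMatrix-class]
#' @export
buildSimilarityMatrix <- function(src, tgt) {
  stopifnot(is(src, "NodeEmbeddings"), is(tgt, "NodeEmbeddings"))
  A <- src@vectors; B <- tgt@vectors
  if (ncol(A) != ncol(B))
    stop("embedding dimensions differ between source (", ncol(A),
         ") and target (", ncol(B), ")")
  an <- sqrt(rowSums(A^2)); bn <- sqrt(rowSums(B^2))
  if (any(an == 0) || any(bn == 0))
    stop("zero embedding vector encountered")
  S <- (A / an) %*% t(B / bn)
  # numerical guard: keep cosine values inside [-1, 1]
  S[S > 1] <- 1; S[S < -1] <- -1
  new("SimilarityMatrix", values = S)
}

#' @describeIn buildSimilarityMatrix the raw similarity matrix
#' @param x a [SimilarityMatrix-class]
#' @export
setMethod("values", "SimilarityMatrix", function(x) x@values)

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix:", nrow(object@values), "source x",
      ncol(object@values), "target nodes; range [",
      sprintf("%.4f", min(object@values)), ",",
      sprintf("%.4f", max(object@values)), "]\n")
})

#' Read / write a labelled similarity matrix
#'
#' The on-disk layout is a labelled table: first row holds target-node
#' labels, first column source-node labels. Tab- and comma-separated files
#' are both accepted on read; writes are tab-separated.
#'
#' @param path file path
#' @return a [SimilarityMatrix-class]
#' @export
readSimilarityMatrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse similarity matrix: ",
                             conditionMessage(e)))
  rn <- as.character(tab[[1]])
  if (anyDuplicated(rn)) stop("duplicate source labels in similarity matrix")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in similarity matrix")
  rownames(m) <- rn
  new("SimilarityMatrix", values = m)
}

#' @rdname readSimilarityMatrix
#' @param S a [SimilarityMatrix-class]
#' @export
writeSimilarityMatrix <- function(S, path) {
  stopifnot(is(S, "SimilarityMatrix"))
  m <- S@values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("node", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i],
                       formatC(m[i, ], format = "g", digits = 10)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Greedy one-to-one pre-mapping from a similarity matrix
#'
#' Candidate pairs are processed in strictly descending similarity order
#' (ties broken lexicographically by source then target label); a pair is
#' accepted when both endpoints are still unmatched. This realizes the
#' global maximization of the mapping objective: a node pair is fixed only
#' when no remaining pair scores higher, and collisions resolve in favor of
#' the globally best pair.
#'
#' @param S a [SimilarityMatrix-class]
#' @return an [Alignment-class] with one pair per source node (when the
#'   target side is at least as large)
#' @export
preMapping <- function(S) {
  stopifnot(is(S, "SimilarityMatrix"))
  m <- S@values
  nr <- nrow(m); nc <- ncol(m)
  if (nr == 0 || nc == 0)
    return(new("Alignment",
               pairs = data.frame(source = character(0), target = character(0),
                                  score = numeric(0), stringsAsFactors = FALSE)))
  ri <- rep(seq_len(nr), times = nc)
  ci <- rep(seq_len(nc), each = nr)
  o <- order(-as.vector(m), rownames(m)[ri], colnames(m)[ci],
             method = "radix")
  srcFree <- rep(TRUE, nr); tgtFree <- rep(TRUE, nc)
  need <- min(nr, nc); got <- 0L
  src <- integer(need); tgt <- integer(need)
  for (k in o) {
    i <- ri[k]; j <- ci[k]
    if (srcFree[i] && tgtFree[j]) {
      got <- got + 1L
      src[got] <- i; tgt[got] <- j
      srcFree[i] <- FALSE; tgtFree[j] <- FALSE
      if (got == need) break
    }
  }
  pairs <- data.frame(source = rownames(m)[src], target = colnames(m)[tgt],
                      score = m[cbind(src, tgt)], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$source, method = "radix"), , drop = FALSE]
  rownames(pairs) <- NULL
  new("Alignment", pairs = pairs, permutationsUsed = 0L, stopReason = "none")
}

# Fast Jaccard machinery shared by refineAlignment() and
# jaccardCoefficient(). All node sets are integer-encoded; the target-side
# neighborhood is held as a logical membership matrix so one Jc evaluation
# is a couple of vectorized lookups.
.jaccardContext <- function(srcNet, tgtNet) {
  sa <- .adjacency(srcNet)
  ta <- .adjacency(tgtNet)
  nT <- length(ta$nodes)
  mask <- matrix(FALSE, nT, nT)
  for (u in seq_len(nT)) mask[ta$adj[[u]], u] <- TRUE
  list(srcNodes = sa$nodes, tgtNodes = ta$nodes, srcAdj = sa$adj,
       tgtAdj = ta$adj, tgtMask = mask, tgtDeg = lengths(ta$adj))
}

# mp: integer vector over source indices -> target indices (NA = unmapped)
.jc <- function(ctx, i, u, mp) {
  img <- mp[ctx$srcAdj[[i]]]
  un <- sum(is.na(img))
  img <- img[!is.na(img)]
  inter <- sum(ctx$tgtMask[img, u])
  uni <- length(img) + ctx$tgtDeg[u] - inter + un
  if (uni == 0) return(0)
  inter / uni
}

#' Jaccard coefficient of a candidate node pair under a mapping
#'
#' \code{Jc = |G(u) n G(v)| / |G(u) u G(v)|} over neighbor sets, where the
#' neighbors of the source node \code{v} are first translated into the
#' target network through the current alignment (a neighbor without an
#' image counts toward the union only). When the two networks share node
#' identifiers and the mapping is the identity, translation is the
#' identity. Result lies in \[0, 1\]; 1 means the mapped neighborhoods
#' overlap perfectly.
#'
#' @param srcNet,tgtNet the two [MultilayerNetwork-class] objects
#' @param v source node, \code{u} target node
#' @param u target node
#' @param current an [Alignment-class] providing the translation
#' @return numeric scalar in \[0, 1\]
#' @export
jaccardCoefficient <- function(srcNet, tgtNet, v, u, current) {
  ctx <- .jaccardContext(srcNet, tgtNet)
  i <- match(v, ctx$srcNodes)
  ui <- match(u, ctx$tgtNodes)
  if (is.na(i)) stop("unknown source node: ", v)
  if (is.na(ui)) stop("unknown target node: ", u)
  p <- current@pairs
  mp <- rep(NA_integer_, length(ctx$srcNodes))
  mp[match(p$source, ctx$srcNodes)] <- match(p$target, ctx$tgtNodes)
  .jc(ctx, i, ui, mp)
}

#' Refine a pre-mapping by Jaccard-guided permutations
#'
#' Pairs whose Jaccard coefficient is already 1 are frozen: their mapped
#' neighborhoods overlap perfectly and need no further optimization. The
#' remaining pairs are revisited in ascending-Jc order; for each, the swap
#' with another non-frozen pair that most increases the total Jaccard
#' coefficient is applied, provided total mapped embedding similarity does
#' not drop by more than \code{similarityTolerance}. By default the
#' tolerance is \code{Inf}: a permutation may trade embedding similarity
#' for strictly better global neighborhood overlap, which is what drives
#' node-correctness recovery on noisy counterparts. Iteration stops when a
#' full pass accepts no swap, when every pair reaches Jc = 1, or when the
#' budget of accepted permutations is exhausted (default: 50\% of the
#' pre-mapping size).
#'
#' @param S the [SimilarityMatrix-class] the pre-mapping came from
#' @param pre an [Alignment-class] (one-to-one)
#' @param srcNet,tgtNet the two networks
#' @param maxPermutations accepted-swap budget; \code{NULL} means
#'   \code{ceiling(0.5 * nrow(pairs))}
#' @param similarityTolerance maximum allowed decrease of total mapped
#'   similarity per swap (default \code{Inf}, i.e. unconstrained)
#' @return an [Alignment-class] with a \code{jaccard} column,
#'   \code{permutationsUsed} and \code{stopReason} filled in
#' @export
refineAlignment <- function(S, pre, srcNet, tgtNet, maxPermutations = NULL,
                            similarityTolerance = Inf) {
  stopifnot(is(S, "SimilarityMatrix"), is(pre, "Alignment"))
  p <- pre@pairs
  n <- nrow(p)
  budget <- if (is.null(maxPermutations)) ceiling(0.5 * n)
            else as.integer(maxPermutations)
  if (budget < 0) stop("permutation budget must be non-negative")
  ctx <- .jaccardContext(srcNet, tgtNet)
  si <- match(p$source, ctx$srcNodes)
  ti <- match(p$target, ctx$tgtNodes)
  if (anyNA(si) || anyNA(ti))
    stop("alignment references nodes absent from the networks")
  mp <- rep(NA_integer_, length(ctx$srcNodes))
  mp[si] <- ti
  Sv <- S@values
  simOf <- function(i, u) Sv[ctx$srcNodes[i], ctx$tgtNodes[u]]

  jcAll <- function(mp) vapply(seq_len(n), function(k)
    .jc(ctx, si[k], mp[si[k]], mp), numeric(1))
  jc <- jcAll(mp)
  used <- 0L
  reason <- "converged"
  if (budget == 0L) {
    reason <- "budget_exhausted"
  } else repeat {
    frozen <- jc >= 1
    if (all(frozen)) { reason <- "all_overlapped"; break }
    accepted <- FALSE
    for (k in order(jc, method = "radix")) {
      if (jc[k] >= 1) next
      open <- which(jc < 1)
      open <- open[open != k]
      if (!length(open)) break
      best <- 0; bestJ <- NA_integer_
      for (j in open) {
        mp2 <- mp
        mp2[si[k]] <- ti[j]; mp2[si[j]] <- ti[k]
        d <- .jc(ctx, si[k], ti[j], mp2) + .jc(ctx, si[j], ti[k], mp2) -
             jc[k] - jc[j]
        if (d > best + 1e-12) {
          dSim <- simOf(si[k], ti[j]) + simOf(si[j], ti[k]) -
                  simOf(si[k], ti[k]) - simOf(si[j], ti[j])
          if (dSim >= -similarityTolerance) { best <- d; bestJ <- j }
        }
      }
      if (!is.na(bestJ)) {
        mp2 <- mp
        mp2[si[k]] <- ti[bestJ]; mp2[si[bestJ]] <- ti[k]
        jc2 <- jcAll(mp2)
        # the local gain must survive the mapping-wide translation effect
        if (sum(jc2) > sum(jc) + 1e-12) {
          tmp <- ti[k]; ti[k] <- ti[bestJ]; ti[bestJ] <- tmp
          mp <- mp2; jc <- jc2
          used <- used + 1L
          accepted <- TRUE
          if (used >= budget) break
        }
      }
    }
    if (used >= budget && !all(jc >= 1)) { reason <- "budget_exhausted"; break }
    if (all(jc >= 1)) { reason <- "all_overlapped"; break }
    if (!accepted) { reason <- "converged"; break }
  }
  out <- data.frame(source = ctx$srcNodes[si], target = ctx$tgtNodes[ti],
                    score = Sv[cbind(ctx$srcNodes[si], ctx$tgtNodes[ti])],
                    jaccard = jc, stringsAsFactors = FALSE)
  out <- out[order(out$source, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  new("Alignment", pairs = out, permutationsUsed = used, stopReason = reason)
}

#' Pairwise global alignment of two multilayer networks
#'
#' The full pipeline: embed both networks independently (or accept an
#' external similarity matrix, bypassing the random-walk evaluation), build
#' the cosine similarity matrix, extract the greedy one-to-one pre-mapping
#' and refine it by Jaccard-guided permutations. When the source network
#' has more nodes than the target the two are swapped internally and the
#' mapping inverted on output, so rows of the result always cover the
#' smaller node set.
#'
#' @param srcNet,tgtNet [MultilayerNetwork-class] objects
#' @param embConfig an [embeddingConfig()]; ignored when
#'   \code{externalSimilarity} is given
#' @param externalSimilarity optional [SimilarityMatrix-class] whose labels
#'   must match the two node sets
#' @param maxPermutations see [refineAlignment()]
#' @param refine set \code{FALSE} to stop at the pre-mapping
#' @param similarityTolerance see [refineAlignment()]
#' @return an [Alignment-class], ordered by source node
#' @export
alignNetworks <- function(srcNet, tgtNet, embConfig = embeddingConfig(),
                          externalSimilarity = NULL, maxPermutations = NULL,
                          refine = TRUE, similarityTolerance = Inf) {
  stopifnot(is(srcNet, "MultilayerNetwork"), is(tgtNet, "MultilayerNetwork"))
  swapped <- length(nodeIds(srcNet)) > length(nodeIds(tgtNet))
  if (swapped) { tmp <- srcNet; srcNet <- tgtNet; tgtNet <- tmp }
  if (!is.null(externalSimilarity)) {
    stopifnot(is(externalSimilarity, "SimilarityMatrix"))
    S <- externalSimilarity
    if (swapped) S <- new("SimilarityMatrix", values = t(S@values))
    badR <- setdiff(rownames(S@values), nodeIds(srcNet))
    badC <- setdiff(colnames(S@values), nodeIds(tgtNet))
    if (length(badR) || length(badC))
      stop("similarity matrix labels absent from the networks: ",
           paste(c(badR, badC), collapse = ", "))
    if (!all(nodeIds(srcNet) %in% rownames(S@values)))
      stop("similarity matrix misses source nodes")
  } else {
    S <- buildSimilarityMatrix(embedNetwork(srcNet, embConfig),
                               embedNetwork(tgtNet, embConfig))
  }
  pre <- preMapping(S)
  aln <- if (refine)
    refineAlignment(S, pre, srcNet, tgtNet, maxPermutations,
                    similarityTolerance)
  else pre
  if (swapped) {
    p <- aln@pairs
    inv <- data.frame(source = p$target, target = p$source,
                      score = p$score, stringsAsFactors = FALSE)
    if ("jaccard" %in% names(p)) inv$jaccard <- p$jaccard
    inv <- inv[order(inv$source, method = "radix"), , drop = FALSE]
    rownames(inv) <- NULL
    aln <- new("Alignment", pairs = inv,
               permutationsUsed = aln@permutationsUsed,
               stopReason = aln@stopReason)
  }
  aln
}

#' @describeIn Alignment-class the aligned pairs table
#' @export
setMethod("alignedPairs", "Alignment", function(x) x@pairs)

#' @describeIn Alignment-class accepted permutations during refinement
#' @export
setMethod("permutationsUsed", "Alignment", function(x) x@permutationsUsed)

setMethod("show", "Alignment", function(object) {
  cat("Alignment of", nrow(object@pairs), "node pairs",
      "| permutations:", object@permutationsUsed,
      "| stop:", object@stopReason, "\n")
  if (nrow(object@pairs))
    print(utils::head(object@pairs, 5))
})

#' Read / write an alignment as TSV
#'
#' Columns: \code{source}, \code{target}, \code{score}, and
#' \code{jaccard} when present; header included.
#'
#' @param a an [Alignment-class]
#' @param path file path
#' @export
writeAlignment <- function(a, path) {
  stopifnot(is(a, "Alignment"))
  utils::write.table(a@pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlignment
#' @export
readAlignment <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  new("Alignment", pairs = tab, permutationsUsed = 0L, stopReason = "none")
}

#' Read / write a ground-truth node mapping (two-column TSV, no header)
#' @param mapping data.frame with columns \code{source}, \code{target}
#' @param path file path
#' @export
writeTrueMapping <- function(mapping, path) {
  utils::write.table(mapping[, c("source", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeTrueMapping
#' @export
readTrueMapping <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(tab[, 1:2], c("source", "target"))
}
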