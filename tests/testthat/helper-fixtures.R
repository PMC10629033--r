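# Small fixtures built in code; everything seeded.

# the 3-edge toy: layers 1-2, interlayer 3
toyNet <- function() {
  multilayerNetwork(data.frame(u = c("a", "c", "a"),
                               v = c("b", "d", "c"),
                               layer = c(1L, 2L, 3L)),
                    layerIds = 1:2, interlayerId = 3L)
}

# two triangles joined by two interlayer edges (flat-representation toy)
twoLayerNet <- function() {
  multilayerNetwork(data.frame(
    u     = c("a", "a", "b", "d", "d", "e", "a", "c"),
    v     = c("b", "c", "c", "e", "f", "f", "d", "f"),
    layer = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L)))
}

smallGenNet <- function(seed = 5, n = 40, p = 0.3, q = 0.2) {
  generateMultilayer(generatorConfig(n = n, m = 2, p = p, q = q,
                                     seed = seed))
}

tinyEmbCfg <- function(seed = 1, ...) {
  embeddingConfig(dimensions = 16, numWalks = 5, walkLength = 20,
                  window = 3, epochs = 2, seed = seed, ...)
}

# identity-like similarity matrix over a node set
identitySimilarity <- function(nodes, hi = 1, lo = 0) {
  m <- matrix(lo, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  diag(m) <- hi
  new("SimilarityMatrix", values = m)
}

# independent greedy oracle: repeatedly take the max unmatched entry,
# breaking ties lexicographically by (source, target)
greedyOracle <- function(m) {
  src <- character(0); tgt <- character(0)
  while (length(src) < min(nrow(m), ncol(m))) {
    best <- -Inf; bi <- NA; bj <- NA
    for (i in rownames(m)) {
      if (i %in% src) next
      for (j in colnames(m)) {
        if (j %in% tgt) next
        v <- m[i, j]
        better <- v > best ||
          (v == best && (i < bi || (i == bi && j < bj)))
        if (better) { best <- v; bi <- i; bj <- j }
      }
    }
    src <- c(src, bi); tgt <- c(tgt, bj)
  }
  data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
}

totalJaccard <- function(srcNet, tgtNet, pairs) {
  aln <- new("Alignment", pairs = cbind(pairs, score = 0),
             permutationsUsed = 0L, stopReason = "none")
  sum(vapply(seq_len(nrow(pairs)), function(k)
    jaccardCoefficient(srcNet, tgtNet, pairs$source[k], pairs$target[k], aln),
    numeric(1)))
}
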