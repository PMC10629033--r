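permn <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permn(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  out
}

test_that("cosine similarity matches the closed form", {
  expect_equal(cosineSimilarity(c(3, 4), c(3, 4)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosineSimilarity(1:2, 1:3), "equal length")
})

test_that("similarity matrices have the right shape and bounds", {
  set.seed(1)
  a <- new("NodeEmbeddings",
           vectors = matrix(rnorm(3 * 4), 3, 4,
                            dimnames = list(c("x", "y", "z"), NULL)),
           config = list())
  b <- new("NodeEmbeddings",
           vectors = matrix(rnorm(4 * 4), 4, 4,
                            dimnames = list(c("p", "q", "r", "s"), NULL)),
           config = list())
  S <- buildSimilarityMatrix(a, b)
  expect_equal(dim(values(S)), c(3L, 4L))
  expect_true(all(values(S) >= -1 & values(S) <= 1))
  Saa <- buildSimilarityMatrix(a, a)
  expect_equal(unname(diag(values(Saa))), rep(1, 3))
  bad <- new("NodeEmbeddings",
             vectors = matrix(1, 2, 7, dimnames = list(c("p", "q"), NULL)),
             config = list())
  expect_error(buildSimilarityMatrix(a, bad), "dimensions differ")
})

test_that("labelled similarity matrices round-trip through disk", {
  m <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
              dimnames = list(c("v1", "v2"), c("u1", "u2")))
  S <- new("SimilarityMatrix", values = m)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSimilarityMatrix(S, f)
  expect_equal(values(readSimilarityMatrix(f)), m)
  f2 <- withr::local_tempfile(lines = c("node,u1,u2", "v1,0.9,bad"))
  expect_error(readSimilarityMatrix(f2), "non-numeric")
})

test_that("an external matrix with labels absent from the networks is rejected", {
  net <- toyNet()
  S <- identitySimilarity(c(nodeIds(net)[1:3], "ghost"))
  expect_error(alignNetworks(net, net, externalSimilarity = S), "ghost")
})

test_that("greedy pre-mapping processes pairs in descending order", {
  # identity-like matrix recovers the perfect matching
  S <- identitySimilarity(c("a", "b", "c"))
  expect_equal(alignedPairs(preMapping(S))$target, c("a", "b", "c"))

  # hand-simulated: 0.9 consumes u1, so v2 falls through to u2
  m <- matrix(c(0.9, 0.7, 0.8, 0.1), 2, 2,
              dimnames = list(c("v1", "v2"), c("u1", "u2")))
  p <- alignedPairs(preMapping(new("SimilarityMatrix", values = m)))
  expect_equal(p$target[p$source == "v1"], "u1")
  expect_equal(p$target[p$source == "v2"], "u2")

  # single source row takes its argmax column
  m1 <- matrix(c(0.2, 0.9, 0.5), 1, 3,
               dimnames = list("v", c("u1", "u2", "u3")))
  expect_equal(alignedPairs(preMapping(new("SimilarityMatrix", values = m1)))$target,
               "u2")
})

test_that("greedy equals the descending-order oracle on small instances", {
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(3:6, 1)
    m <- matrix(round(stats::runif(k * k), 3), k, k,
                dimnames = list(sprintf("v%d", 1:k), sprintf("u%d", 1:k)))
    S <- new("SimilarityMatrix", values = m)
    got <- alignedPairs(preMapping(S))[, c("source", "target")]
    oracle <- greedyOracle(m)
    oracle <- oracle[order(oracle$source), ]
    rownames(oracle) <- NULL
    expect_equal(got, oracle)
    # greedy is not claimed optimal: the exhaustive optimum can only be >=
    best <- max(vapply(permn(1:k), function(p)
      sum(m[cbind(1:k, p)]), numeric(1)))
    expect_gte(best, sum(alignedPairs(preMapping(S))$score))
  }
})

test_that("the Jaccard coefficient translates source neighborhoods", {
  src <- multilayerNetwork(data.frame(u = "v", v = c("x1", "x2", "x3"),
                                      layer = 1L),
                           layerIds = 1L, interlayerId = NA)
  tgt <- multilayerNetwork(data.frame(u = c("u", "u", "u", "b"),
                                      v = c("c", "d", "e", "c"),
                                      layer = 1L),
                           layerIds = 1L, interlayerId = NA)
  cur <- new("Alignment",
             pairs = data.frame(source = c("v", "x1", "x2", "x3"),
                                target = c("u", "b", "c", "d"),
                                score = 1),
             permutationsUsed = 0L, stopReason = "none")
  # translated {b,c,d} vs {c,d,e}: 2 shared of 4
  expect_equal(jaccardCoefficient(src, tgt, "v", "u", cur), 0.5)

  net <- toyNet()
  idAln <- new("Alignment",
               pairs = data.frame(source = nodeIds(net),
                                  target = nodeIds(net), score = 1),
               permutationsUsed = 0L, stopReason = "none")
  expect_equal(jaccardCoefficient(net, net, "a", "a", idAln), 1)
  expect_equal(jaccardCoefficient(net, net, "b", "d", idAln), 0)
})

test_that("refinement undoes a crossed pre-mapping via neighborhood overlap", {
  # tree with distinguishable leaves: 3 hangs off the hub, 4 off node 2;
  # the embedding similarity crosses the two leaves, the neighborhood
  # overlap puts them back
  e <- data.frame(u = c("1", "2", "1", "1"), v = c("3", "4", "2", "5"))
  src <- multilayerNetwork(data.frame(u = paste0("s", e$u),
                                      v = paste0("s", e$v), layer = 1L),
                           layerIds = 1L, interlayerId = NA)
  tgt <- multilayerNetwork(data.frame(u = paste0("t", e$u),
                                      v = paste0("t", e$v), layer = 1L),
                           layerIds = 1L, interlayerId = NA)
  m <- matrix(0.1, 5, 5, dimnames = list(sprintf("s%d", 1:5),
                                         sprintf("t%d", 1:5)))
  m["s3", "t4"] <- 0.90; m["s4", "t3"] <- 0.88
  m["s3", "t3"] <- 0.80; m["s4", "t4"] <- 0.80
  m["s1", "t1"] <- 0.85; m["s2", "t2"] <- 0.85; m["s5", "t5"] <- 0.85
  S <- new("SimilarityMatrix", values = m)
  pre <- preMapping(S)
  pp <- alignedPairs(pre)
  expect_equal(pp$target[pp$source == "s3"], "t4")
  expect_equal(pp$target[pp$source == "s4"], "t3")

  ref <- refineAlignment(S, pre, src, tgt)
  p <- alignedPairs(ref)
  expect_equal(p$target, sprintf("t%d", 1:5))   # true mapping restored
  expect_equal(permutationsUsed(ref), 1L)

  # exhaustive check: the refined mapping attains the global Jaccard optimum
  tj <- vapply(permn(1:5), function(perm)
    totalJaccard(src, tgt, data.frame(source = sprintf("s%d", 1:5),
                                      target = sprintf("t%d", perm))),
    numeric(1))
  expect_equal(totalJaccard(src, tgt, p[, 1:2]), max(tj))
})

test_that("refinement respects its budget and never lowers total Jaccard", {
  gen <- smallGenNet(13, n = 40)
  net <- gen$network
  noisy <- perturbEdges(net, 0.25, seed = 1)
  cfg <- tinyEmbCfg(seed = 13)
  S <- buildSimilarityMatrix(embedNetwork(net, cfg),
                             embedNetwork(noisy, cfg))
  pre <- preMapping(S)
  ref <- refineAlignment(S, pre, net, noisy)
  expect_gte(totalJaccard(net, noisy, alignedPairs(ref)[, 1:2]),
             totalJaccard(net, noisy, alignedPairs(pre)[, 1:2]))
  expect_lte(permutationsUsed(ref), ceiling(0.5 * nrow(alignedPairs(pre))))

  ref0 <- refineAlignment(S, pre, net, noisy, maxPermutations = 0)
  expect_equal(alignedPairs(ref0)[, c("source", "target")],
               alignedPairs(pre)[, c("source", "target")])
  expect_equal(permutationsUsed(ref0), 0L)
  expect_error(refineAlignment(S, pre, net, noisy, maxPermutations = -1),
               "non-negative")

  # one-to-one invariant after every stage
  for (a in list(pre, ref)) {
    p <- alignedPairs(a)
    expect_false(anyDuplicated(p$source) > 0)
    expect_false(anyDuplicated(p$target) > 0)
    expect_equal(nrow(p), length(nodeIds(net)))
  }
})

test_that("an already perfect mapping is returned untouched", {
  net <- toyNet()
  S <- identitySimilarity(nodeIds(net))
  pre <- preMapping(S)
  ref <- refineAlignment(S, pre, net, net)
  expect_equal(alignedPairs(ref)$target, alignedPairs(pre)$target)
  expect_equal(permutationsUsed(ref), 0L)
  expect_equal(ref@stopReason, "all_overlapped")
  expect_true(all(alignedPairs(ref)$jaccard == 1))
})

test_that("self-alignment under an identity similarity is exact", {
  net <- smallGenNet(21, n = 30)$network
  S <- identitySimilarity(nodeIds(net))
  aln <- alignNetworks(net, net, externalSimilarity = S)
  truth <- data.frame(source = nodeIds(net), target = nodeIds(net))
  expect_equal(nodeCorrectness(aln, truth), 1)
  expect_true(all(alignedPairs(aln)$score == 1))
})

test_that("larger-than-target sources are swapped and inverted on output", {
  big <- multilayerNetwork(data.frame(u = c("A", "A", "B", "C"),
                                      v = c("B", "C", "D", "E"), layer = 1L),
                           layerIds = 1L, interlayerId = NA)
  small <- multilayerNetwork(data.frame(u = c("p", "p"), v = c("q", "r"),
                                        layer = 1L),
                             layerIds = 1L, interlayerId = NA)
  m <- matrix(0.1, 5, 3, dimnames = list(nodeIds(big), nodeIds(small)))
  m["A", "p"] <- 0.9; m["B", "q"] <- 0.9; m["C", "r"] <- 0.9
  aln <- alignNetworks(big, small,
                       externalSimilarity = new("SimilarityMatrix", values = m))
  p <- alignedPairs(aln)
  expect_equal(nrow(p), 3L)                       # the smaller node set
  expect_true(all(p$source %in% nodeIds(big)))
  expect_true(all(p$target %in% nodeIds(small)))
  expect_equal(p$target[p$source == "A"], "p")
})

test_that("alignments round-trip through TSV", {
  net <- toyNet()
  aln <- alignNetworks(net, net,
                       externalSimilarity = identitySimilarity(nodeIds(net)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAlignment(aln, f)
  back <- readAlignment(f)
  expect_equal(alignedPairs(back)$source, alignedPairs(aln)$source)
  expect_equal(alignedPairs(back)$target, alignedPairs(aln)$target)
})
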