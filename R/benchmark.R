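#' Run the synthetic alignment benchmark
#'
#' Reproduces the benchmark protocol end to end: generate multilayer
#' networks (half with each parameter set), derive noisy counterparts by
#' random edge removal at each noise level, align every base network with
#' itself (0\% noise) and with each counterpart, and score the alignments.
#' Node correctness values are min-max normalized over the whole run into
#' alignment scores, summarized per noise level, and passed through the
#' descriptive + one-way-ANOVA machinery (noise groups 5\%..25\%).
#'
#' @param paramSets list of lists with elements \code{p}, \code{q}; the
#'   default is the benchmark's two duplication/divergence settings
#' @param networksPerSet base networks generated per parameter set
#' @param n,m generator size parameters (see [generatorConfig()])
#' @param noiseLevels fractions of edges removed for the noisy counterparts
#' @param includeSelf also run the 0\%-noise self-alignments
#' @param embConfig an [embeddingConfig()]; its seed is overridden per
#'   network with a value derived from \code{seed}
#' @param maxPermutations see [refineAlignment()]
#' @param seed master seed; every generator and embedding seed derives
#'   from it
#' @param verbose print one line per alignment
#' @return list of class \code{BenchmarkResult}: \code{scores} (one row
#'   per alignment: network, set, noise, nc, score), \code{table} (mean
#'   score per noise level plus overall mean), \code{descriptives},
#'   \code{anova}, \code{kpi} (pooled AUC, F1 aggregates, MCC), and the
#'   run parameters
#' @export
runBenchmark <- function(paramSets = list(list(p = 0.5, q = 0.4),
                                          list(p = 0.3, q = 0.7)),
                         networksPerSet = 5, n = 100, m = 2,
                         noiseLevels = c(0.05, 0.10, 0.15, 0.20, 0.25),
                         includeSelf = TRUE,
                         embConfig = embeddingConfig(),
                         maxPermutations = NULL, seed = 1L,
                         verbose = FALSE) {
  stopifnot(length(paramSets) >= 1, networksPerSet >= 1)
  rows <- list()
  countsList <- list()
  pooledScores <- numeric(0)
  pooledLabels <- logical(0)
  pooledNoise <- numeric(0)
  netIdx <- 0L
  for (s in seq_along(paramSets)) {
    ps <- paramSets[[s]]
    for (r in seq_len(networksPerSet)) {
      netIdx <- netIdx + 1L
      netSeed <- (as.integer(seed) + 7919L * netIdx) %% .Machine$integer.max
      gcfg <- generatorConfig(n = n, m = m, p = ps$p, q = ps$q,
                              seed = netSeed)
      gen <- generateMultilayer(gcfg)
      net <- gen$network
      truth <- gen$mapping
      ecfg <- embConfig
      ecfg$seed <- netSeed
      baseEmb <- embedNetwork(net, ecfg)
      levels <- c(if (includeSelf) 0, noiseLevels)
      for (f in levels) {
        tgt <- if (f == 0) net else
          perturbEdges(net, f, seed = netSeed + round(1000 * f))
        tgtEmb <- if (f == 0) baseEmb else embedNetwork(tgt, ecfg)
        S <- buildSimilarityMatrix(baseEmb, tgtEmb)
        pre <- preMapping(S)
        aln <- refineAlignment(S, pre, net, tgt, maxPermutations)
        nc <- nodeCorrectness(aln, truth)
        rows[[length(rows) + 1L]] <-
          data.frame(network = netIdx, set = s, noise = f, nc = nc,
                     permutations = aln@permutationsUsed,
                     stringsAsFactors = FALSE)
        countsList[[length(countsList) + 1L]] <- confusionCounts(aln, truth)
        tm <- .truthMap(truth)
        p <- aln@pairs
        pooledScores <- c(pooledScores, p$score)
        pooledLabels <- c(pooledLabels,
                          !is.na(tm[p$source]) & tm[p$source] == p$target)
        pooledNoise <- c(pooledNoise, f)
        if (verbose)
          message(sprintf("network %d (set %d) noise %4.0f%%: NC = %.3f",
                          netIdx, s, 100 * f, nc))
      }
    }
  }
  scores <- do.call(rbind, rows)
  scores$score <- alignmentScore(scores$nc)
  tab <- tapply(scores$score, scores$noise, mean)
  table <- c(tab, Mean = mean(scores$score))
  noisy <- scores[scores$noise > 0, , drop = FALSE]
  desc <- NULL; aov <- NULL
  if (nrow(noisy) && min(table(noisy$noise)) >= 2) {
    groups <- split(noisy$score, 100 * noisy$noise)
    desc <- descriptiveStats(groups)
    aov <- if (length(groups) >= 2) anovaFromSummary(desc) else NULL
  }
  pooledRoc <- .rocSweep(pooledScores, pooledLabels)
  f1 <- f1Scores(countsList, vapply(rows, function(r) r$noise, numeric(1)))
  pooledCounts <- Reduce(`+`, countsList)
  structure(list(scores = scores, table = table, descriptives = desc,
                 anova = aov,
                 kpi = list(auc = pooledRoc$auc, f1_avg = f1$f1_avg,
                            f1_max = f1$f1_max, f1_norm = f1$f1_norm,
                            mcc = mcc(pooledCounts)),
                 seed = seed, n = n, m = m, paramSets = paramSets,
                 networksPerSet = networksPerSet,
                 noiseLevels = noiseLevels),
            class = "BenchmarkResult")
}

#' @export
print.BenchmarkResult <- function(x, ...) {
  cat("BenchmarkResult:", nrow(x$scores), "alignments (seed", x$seed, ")\n")
  cat("Mean alignment score by noise level:\n")
  print(round(x$table, 3))
  if (!is.null(x$anova))
    cat(sprintf("ANOVA over noise groups: F = %.5f, p = %.5g\n",
                x$anova$F, x$anova$p))
  invisible(x)
}
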