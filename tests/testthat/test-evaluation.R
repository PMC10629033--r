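mkAln <- function(src, tgt, score = seq(1, 0.5, length.out = length(src))) {
  new("Alignment", pairs = data.frame(source = src, target = tgt,
                                      score = score,
                                      stringsAsFactors = FALSE),
      permutationsUsed = 0L, stopReason = "none")
}
idTruth <- function(nodes) data.frame(source = nodes, target = nodes)

test_that("node correctness is the matched fraction of the truth", {
  n <- sprintf("n%03d", 1:100)
  expect_equal(nodeCorrectness(mkAln(n, n), idTruth(n)), 1)
  half <- c(n[1:50], rev(n[51:100]))
  expect_equal(nodeCorrectness(mkAln(n, half), idTruth(n)), 0.5)
  expect_error(nodeCorrectness(mkAln(n, n), idTruth(character(0))), "empty")

  # invariance under consistent relabeling of both sides
  lab <- setNames(sprintf("x%03d", 1:100), n)
  expect_equal(nodeCorrectness(mkAln(unname(lab[n]), unname(lab[half])),
                               data.frame(source = unname(lab[n]),
                                          target = unname(lab[n]))),
               0.5)
})

test_that("alignment score is unity-based min-max scaling", {
  expect_equal(alignmentScore(c(0.2, 0.6, 1.0)), c(0, 0.5, 1))
  expect_equal(alignmentScore(1.0), 1.0)      # degenerate: raw value kept
  expect_equal(alignmentScore(c(0.3, 0.3)), c(0.3, 0.3))
  s <- alignmentScore(runif(20))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("confusion counts follow the forced one-to-one convention", {
  n <- sprintf("n%d", 1:10)
  expect_equal(confusionCounts(mkAln(n, n), idTruth(n)),
               c(tp = 10L, fp = 0L, tn = 0L, fn = 0L))
  shift <- c(n[-1], n[1])
  expect_equal(confusionCounts(mkAln(n, shift), idTruth(n)),
               c(tp = 0L, fp = 10L, tn = 0L, fn = 10L))
  seven <- c(n[1:7], n[c(9, 10, 8)])
  expect_equal(confusionCounts(mkAln(n, seven), idTruth(n)),
               c(tp = 7L, fp = 3L, tn = 0L, fn = 3L))
})

test_that("ROC sweep matches the rank-statistic oracle", {
  n <- sprintf("n%d", 1:8)
  tgt <- c(n[1:6], n[c(8, 7)])            # two wrong pairs
  # perfectly separating scores
  aln <- mkAln(n, tgt, score = c(rep(0.9, 6), 0.1, 0.2))
  expect_equal(rocAuc(aln, idTruth(n))$auc, 1)
  # all-equal scores anchor at chance
  expect_equal(rocAuc(mkAln(n, tgt, score = rep(0.5, 8)), idTruth(n))$auc, 0.5)

  # one inversion: compare against brute-force threshold enumeration and
  # the Mann-Whitney statistic
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.6, 0.5, 0.4, 0.2)
  aln2 <- mkAln(n, tgt, score = scores)
  labels <- c(rep(TRUE, 6), FALSE, FALSE)
  sweep <- function(scores, labels) {
    pts <- unique(rbind(c(0, 0),
      do.call(rbind, lapply(sort(unique(scores), decreasing = TRUE),
        function(th) c(sum(scores >= th & !labels) / sum(!labels),
                       sum(scores >= th & labels) / sum(labels)))),
      c(1, 1)))
    sum(diff(pts[, 1]) * (head(pts[, 2], -1) + tail(pts[, 2], -1)) / 2)
  }
  expect_equal(rocAuc(aln2, idTruth(n))$auc, sweep(scores, labels))
  u <- sum(outer(scores[labels], scores[!labels], ">")) +
    0.5 * sum(outer(scores[labels], scores[!labels], "=="))
  expect_equal(rocAuc(aln2, idTruth(n))$auc, u / (6 * 2))

  curve <- rocAuc(aln2, idTruth(n))$curve
  expect_equal(unlist(curve[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(curve[nrow(curve), ]), c(fpr = 1, tpr = 1))
})

test_that("F1 aggregates combine precision and recall harmonically", {
  perfect <- c(tp = 5L, fp = 0L, tn = 0L, fn = 0L)
  r <- f1Scores(list(perfect, perfect), c(5, 10))
  expect_equal(unlist(r[c("f1_avg", "f1_max", "f1_norm")]),
               c(f1_avg = 1, f1_max = 1, f1_norm = 1))
  # precision 1, recall 0.5 -> 2/3
  r2 <- f1Scores(list(c(tp = 5L, fp = 0L, tn = 0L, fn = 5L)), "5")
  expect_equal(r2$f1_avg, 2 / 3)
  expect_equal(f1Scores(list(c(tp = 0L, fp = 4L, tn = 0L, fn = 4L)),
                        "5")$f1_avg, 0)
})

test_that("MCC follows the contingency closed form", {
  expect_equal(mcc(c(tp = 7L, fp = 0L, tn = 7L, fn = 0L)), 1)
  expect_equal(mcc(c(tp = 0L, fp = 7L, tn = 0L, fn = 7L)), -1)
  expect_equal(mcc(c(tp = 5L, fp = 5L, tn = 5L, fn = 5L)), 0)
  expect_equal(mcc(c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)), 0)
  # antisymmetry under swapping predictions
  cnt <- c(tp = 8L, fp = 2L, tn = 6L, fn = 4L)
  expect_equal(mcc(cnt), -mcc(c(tp = cnt[["fp"]], fp = cnt[["tp"]],
                                tn = cnt[["fn"]], fn = cnt[["tn"]])))
})

test_that("evaluateAlignment assembles consistent KPIs", {
  n <- sprintf("n%d", 1:10)
  tgt <- c(n[1:8], n[c(10, 9)])
  aln <- mkAln(n, tgt, score = seq(0.95, 0.5, length.out = 10))
  rep <- evaluateAlignment(aln, idTruth(n))
  expect_equal(rep@nc, 0.8)
  expect_equal(rep@counts[["tp"]], 8L)
  expect_equal(rep@tpr, 0.8)
  expect_equal(rep@f1, 0.8)
})

test_that("percentage improvement is plain relative change", {
  expect_equal(percentImprovement(0.6, 0.3), 100)
  expect_error(percentImprovement(1, 0))
})

test_that("summary ANOVA equals raw-data ANOVA and the stats oracle", {
  set.seed(42)
  groups <- list(a = rnorm(8, 0.5, 0.1), b = rnorm(10, 0.7, 0.15),
                 c = rnorm(9, 0.4, 0.1))
  fromSummary <- anovaFromSummary(descriptiveStats(groups))
  fromRaw <- anovaFromRaw(groups)
  expect_equal(fromSummary, fromRaw)

  df <- data.frame(y = unlist(groups),
                   g = rep(names(groups), lengths(groups)))
  ref <- anova(stats::aov(y ~ g, data = df))
  expect_equal(fromSummary$F, ref$`F value`[1])
  expect_equal(fromSummary$p, ref$`Pr(>F)`[1])
  expect_equal(fromSummary$ss_between, ref$`Sum Sq`[1])
  expect_equal(fromSummary$ss_within, ref$`Sum Sq`[2])

  equal <- data.frame(n = c(5, 5), mean = c(1, 1), sd = c(0.1, 0.1))
  expect_equal(anovaFromSummary(equal)$ss_between, 0)
  expect_equal(anovaFromSummary(equal)$F, 0)
})

test_that("McNemar with continuity correction matches the stats oracle", {
  got <- mcnemarTest(8, 31)
  ref <- stats::mcnemar.test(matrix(c(61, 31, 8, 0), 2, 2), correct = TRUE)
  expect_equal(got$chi2, unname(ref$statistic))
  expect_equal(got$p, unname(ref$p.value))
  # b = c: the correction leaves 1/(b+c)
  expect_equal(mcnemarTest(6, 6)$chi2, 1 / 12)
  expect_equal(mcnemarTest(0, 10)$chi2, 8.1)
  expect_error(mcnemarTest(0, 0), "undefined")
  expect_lte(mcnemarTest(8, 31, exact = TRUE)$p, 1)
})

test_that("descriptive statistics use the sample SD", {
  d <- descriptiveStats(list(flat = c(1, 1, 1, 1)))
  expect_equal(d$mean, 1); expect_equal(d$sd, 0); expect_equal(d$cv, 0)
  set.seed(3)
  d2 <- descriptiveStats(list(a = rnorm(10), b = rnorm(7, 2)))
  expect_equal(d2$se, d2$sd / sqrt(d2$n))
  expect_equal(d2$cv, d2$sd / d2$mean)
  expect_error(descriptiveStats(list(one = 1)), "at least 2")
})
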