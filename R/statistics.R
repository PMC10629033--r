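#' Descriptive statistics per group
#'
#' Sample mean, sample SD (n-1 denominator), standard error
#' \code{sd/sqrt(n)} and coefficient of variation \code{sd/mean} for each
#' group of alignment scores.
#'
#' @param groups named list of numeric vectors (names are group labels,
#'   e.g. noise levels); every group needs at least two values
#' @return data.frame with columns \code{label}, \code{n}, \code{mean},
#'   \code{sd}, \code{se}, \code{cv}
#' @export
descriptiveStats <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  rows <- lapply(names(groups), function(lab) {
    x <- groups[[lab]]
    if (length(x) < 2)
      stop("group '", lab, "' needs at least 2 values for a sample SD")
    m <- mean(x); s <- stats::sd(x)
    data.frame(label = lab, n = length(x), mean = m, sd = s,
               se = s / sqrt(length(x)),
               cv = if (m == 0) NA_real_ else s / m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-way ANOVA from per-group summary statistics
#'
#' Recovers the full ANOVA table from group sizes, means and SDs alone —
#' the form needed when only published summary tables are available:
#' \deqn{SS_{between} = \sum_i n_i (\bar x_i - \bar x)^2, \quad
#'       SS_{within} = \sum_i (n_i - 1) s_i^2}
#' with \code{F = MS_between / MS_within} on \code{(k - 1, N - k)} degrees
#' of freedom and the p value from the upper tail of the F distribution.
#' Zero within-group variance with unequal means reports \code{F = Inf},
#' \code{p = 0}.
#'
#' @param groups data.frame with columns \code{n}, \code{mean}, \code{sd}
#'   (one row per group, at least two groups, each \code{n >= 2}); the
#'   output of [descriptiveStats()] qualifies
#' @return list of class \code{AnovaResult}: \code{ss_between},
#'   \code{ss_within}, \code{df_between}, \code{df_within},
#'   \code{ms_between}, \code{ms_within}, \code{F}, \code{p}
#' @export
anovaFromSummary <- function(groups) {
  stopifnot(all(c("n", "mean", "sd") %in% names(groups)),
            nrow(groups) >= 2, all(groups$n >= 2))
  n <- groups$n; m <- groups$mean; s <- groups$sd
  N <- sum(n); k <- nrow(groups)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  dfb <- k - 1L; dfw <- N - k
  msb <- ssb / dfb; msw <- ssw / dfw
  if (msw == 0) {
    Fv <- if (ssb > 0) Inf else 0
    p <- if (ssb > 0) 0 else 1
  } else {
    Fv <- msb / msw
    p <- stats::pf(Fv, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(ss_between = ssb, ss_within = ssw, df_between = dfb,
                 df_within = as.integer(dfw), ms_between = msb,
                 ms_within = msw, F = Fv, p = p),
            class = "AnovaResult")
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat("One-way ANOVA (from summaries)\n")
  cat(sprintf("  Between: SS=%.5f df=%d MS=%.5f\n",
              x$ss_between, x$df_between, x$ms_between))
  cat(sprintf("  Within:  SS=%.5f df=%d MS=%.5f\n",
              x$ss_within, x$df_within, x$ms_within))
  cat(sprintf("  F=%.5f  p=%.5g\n", x$F, x$p))
  invisible(x)
}

#' One-way ANOVA from raw per-group values
#'
#' Convenience route through [descriptiveStats()] +
#' [anovaFromSummary()]; with raw data both routes are identical.
#'
#' @inheritParams descriptiveStats
#' @return an \code{AnovaResult}
#' @export
anovaFromRaw <- function(groups) {
  anovaFromSummary(descriptiveStats(groups))
}

#' McNemar's test with continuity correction
#'
#' Paired-proportions test on the two discordant cells \code{b} and
#' \code{c} of a 2x2 contingency table:
#' \deqn{\chi^2 = (|b - c| - 1)^2 / (b + c)}
#' with the two-tailed p value from the chi-square distribution on 1
#' degree of freedom. The continuity-corrected chi-square is inherently
#' two-sided. An exact binomial variant (\code{exact = TRUE}) is available:
#' \code{2 * P(X <= min(b, c))} for \code{X ~ Binom(b + c, 1/2)}, capped
#' at 1.
#'
#' @param b,c the discordant cell counts
#' @param exact use the exact binomial test instead
#' @return list with \code{chi2} (NA for the exact variant) and \code{p}
#' @examples
#' mcnemarTest(8, 31)   # p ~ 0.0004
#' @export
mcnemarTest <- function(b, c, exact = FALSE) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) stop("McNemar's test undefined: no discordant pairs")
  if (exact) {
    p <- min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
    return(list(chi2 = NA_real_, p = p))
  }
  chi2 <- (abs(b - c) - 1)^2 / (b + c)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
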