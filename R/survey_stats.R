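# Survey-level mislabeling statistics: exact binomial rate estimates,
# channel/year breakdowns, and a two-period comparison.

testable <- function(results) {
  keep <- vapply(results, function(r)
    r$sample_type == "caviar" &&
      r$verdict %in% c("consistent", "mislabeled", "mixed"), logical(1))
  results[keep]
}

#' Survey mislabeling rate with exact confidence interval
#'
#' The denominator is caviar lots with a resolvable final call
#' (extraction-failed, unresolved and non-caviar samples are excluded);
#' "mixed" lots (some eggs consistent, some not) count as mislabeled in the
#' headline rate and are also reported separately. The 95% CI is the exact
#' Clopper-Pearson interval from inverting binomial tail probabilities.
#'
#' @param results a `survey_results` (or list of `lot_result`s).
#' @param conf_level confidence level (default 0.95).
#' @return a `survey_summary`: list with `n_tested`, `n_mislabeled`
#'   (including mixed), `n_mixed`, `rate` (percent), `ci` (percent,
#'   length 2).
#' @export
mislabeling_rate <- function(results, conf_level = 0.95) {
  tst <- testable(results)
  n <- length(tst)
  if (n == 0) stop("no testable lots")
  verdicts <- vapply(tst, `[[`, character(1), "verdict")
  m <- sum(verdicts %in% c("mislabeled", "mixed"))
  ci <- 100 * as.numeric(binom.test(m, n, conf.level = conf_level)$conf.int)
  structure(list(n_tested = n, n_mislabeled = m,
                 n_mixed = sum(verdicts == "mixed"),
                 rate = 100 * m / n, ci = ci, conf_level = conf_level),
            class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("%d of %d lots mislabeled: %.1f%% (exact %g%% CI %.1f-%.1f%%)\n",
              x$n_mislabeled, x$n_tested, x$rate, 100 * x$conf_level,
              x$ci[1], x$ci[2]))
  invisible(x)
}

#' Mislabeling rate by stratum
#'
#' Partitions testable lots by purchase channel or year and computes the
#' per-stratum [mislabeling_rate()]; stratum counts always reconcile with
#' the overall summary.
#'
#' @param results a `survey_results`.
#' @param key "channel" or "year".
#' @return named list of `survey_summary`, one per stratum, with the
#'   overall summary attached as attribute `"overall"`.
#' @export
survey_breakdown <- function(results, key = c("channel", "year")) {
  key <- match.arg(key)
  tst <- testable(results)
  vals <- vapply(tst, function(r) as.character(r[[key]]), character(1))
  if (anyNA(vals)) stop("missing ", key, " on some lots")
  out <- lapply(split(tst, vals), mislabeling_rate)
  attr(out, "overall") <- mislabeling_rate(results)
  out
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' Compare mislabeling between two survey periods
#'
#' Difference in mislabeling rates (percentage points, period a minus
#' period b), an exact conditional test (Fisher's exact test, i.e. the
#' hypergeometric distribution of the 2x2 table), and a CI for the
#' difference by Newcombe's method (combining the two Wilson score
#' intervals). Historical baselines enter as plain counts — nothing is
#' recomputed from the earlier study's data.
#'
#' @param a,b numeric length-2 vectors `c(n_mislabeled, n_tested)`.
#' @param conf_level confidence level.
#' @return a `period_comparison`: list with `rate_a`, `rate_b`,
#'   `difference` (percent), `ci` (percent), `p_value`.
#' @export
compare_periods <- function(a, b, conf_level = 0.95) {
  stopifnot(length(a) == 2, length(b) == 2, a[2] > 0, b[2] > 0,
            a[1] >= 0, b[1] >= 0, a[1] <= a[2], b[1] <= b[2])
  p1 <- a[1] / a[2]; p2 <- b[1] / b[2]
  tab <- matrix(c(a[1], a[2] - a[1], b[1], b[2] - b[1]), 2, 2)
  pv <- fisher.test(tab)$p.value
  w1 <- wilson_ci(a[1], a[2], conf_level)
  w2 <- wilson_ci(b[1], b[2], conf_level)
  d <- p1 - p2
  lo <- d - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2)
  hi <- d + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2)
  structure(list(rate_a = 100 * p1, rate_b = 100 * p2,
                 difference = 100 * d, ci = 100 * c(lo, hi), p_value = pv),
            class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf("%.1f%% vs %.1f%%: difference %.1f points (CI %.1f to %.1f), exact p = %.3g\n",
              x$rate_a, x$rate_b, x$difference, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}
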