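#' Round half away from zero
#'
#' Commercial rounding used in the report layer (base `round()` rounds half
#' to even). Applied only when serializing reports; internal computation
#' keeps full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2, the survey's printed precision).
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(0.015)  # 0.02, where round() gives 0.01
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Descriptive statistics of a concentration series
#'
#' Count, range, median, mean and sample standard deviation (n - 1
#' denominator) of a series of concentrations. `NA` entries (e.g. wells
#' excluded under the `exclude` ND policy) are dropped before computation.
#' For even n the median is the midpoint of the two central order
#' statistics.
#'
#' @param values Numeric concentrations in mg/L; at least one non-`NA`,
#'   all non-negative.
#' @return A `conc_summary` list: `n`, `min`, `max`, `median`, `mean`, `sd`
#'   (all in mg/L; `sd` is `NA` for n = 1). Values are full precision; the
#'   print method rounds to 2 decimals, half away from zero.
#' @examples
#' summarize_conc(c(1, 2, 3, 4))
#' @export
summarize_conc <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("cannot summarize an empty series")
  if (any(values < 0)) stop("concentrations must be non-negative")
  structure(list(n = length(values),
                 min = min(values), max = max(values),
                 median = stats::median(values), mean = mean(values),
                 sd = if (length(values) > 1L) stats::sd(values) else NA_real_),
            class = "conc_summary")
}

#' @export
print.conc_summary <- function(x, digits = 2, ...) {
  r <- function(v) format(round_half_away(v, digits), nsmall = digits)
  cat("Concentration summary (n = ", x$n, ")\n", sep = "")
  cat("  range  ", r(x$min), "-", r(x$max), " mg/L\n", sep = "")
  cat("  median ", r(x$median), " mg/L\n", sep = "")
  cat("  mean   ", r(x$mean), if (!is.na(x$sd))
    paste0(" ± ", r(x$sd)) else "", " mg/L\n", sep = "")
  invisible(x)
}

#' Standard-limit exceedance screening
#'
#' Counts wells whose concentration strictly exceeds a regulatory limit
#' ("higher than" is read as a strict inequality, so a well exactly at the
#' limit does not exceed). Under `rule = "average"` the per-well seasonal
#' average is compared; under `rule = "any_season"` a well exceeds if either
#' resolved season value does. Wells with no resolvable value (all seasons
#' censored under `exclude`) are removed from the denominator.
#'
#' @param x A [well_table()].
#' @param analyte `"nitrate"` or `"nitrite"`.
#' @param limit Standard limit in mg/L (> 0 unless screening is degenerate).
#' @param rule `"average"` (default) or `"any_season"`.
#' @param policy ND policy, see [nd_policies()].
#' @return An `exceedance_result` list: `analyte`, `limit`, `rule`, `count`,
#'   `n` (denominator) and `fraction`.
#' @examples
#' exceedance(divandarreh_wells(), "nitrate", limit = 50)
#' @export
exceedance <- function(x, analyte = ANALYTES, limit,
                       rule = c("average", "any_season"),
                       policy = "exclude") {
  analyte <- match.arg(analyte)
  rule <- match.arg(rule)
  if (!is.numeric(limit) || length(limit) != 1L || limit < 0)
    stop("limit must be a single non-negative number (mg/L)")
  if (rule == "average") {
    v <- seasonal_average(x, analyte, policy = policy)
    keep <- !is.na(v)
    hits <- v[keep] > limit
  } else {
    sp <- resolve_column(x, analyte, "spring", policy)
    au <- resolve_column(x, analyte, "autumn", policy)
    keep <- !(is.na(sp) & is.na(au))
    hits <- (!is.na(sp[keep]) & sp[keep] > limit) |
      (!is.na(au[keep]) & au[keep] > limit)
  }
  n <- sum(keep)
  structure(list(analyte = analyte, limit = limit, rule = rule,
                 count = sum(hits), n = n, fraction = sum(hits) / n),
            class = "exceedance_result")
}

#' @export
print.exceedance_result <- function(x, ...) {
  cat(sprintf("%s > %g mg/L (%s rule): %d of %d wells (%.1f%%)\n",
              x$analyte, x$limit, x$rule, x$count, x$n, 100 * x$fraction))
  invisible(x)
}

new_test_result <- function(method, statistic, p_value, df = NA_real_,
                            estimate = NULL, note = NULL) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), df = unname(df),
                 estimate = estimate,
                 conclusion_at_0p05 = unname(p_value) < 0.05,
                 note = note),
            class = "nitrorisk_test")
}

#' @export
print.nitrorisk_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$estimate))
    cat("  estimate =", format(x$estimate, digits = 4), "\n")
  cat("  statistic =", format(x$statistic, digits = 4),
      if (!is.na(x$df)) paste0(" (df = ", format(x$df, digits = 4), ")"),
      ", p =", format(x$p_value, digits = 4), "\n")
  cat("  significant at 0.05:", x$conclusion_at_0p05, "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' One-sample t test against a standard value
#'
#' Student's t test of the mean of a concentration series against a
#' hypothesized value, typically a drinking-water standard limit.
#'
#' @param values Numeric series (mg/L); `NA` dropped; needs n >= 2 and
#'   non-zero spread.
#' @param mu0 Hypothesized mean (mg/L).
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @return A `nitrorisk_test` with `statistic` (t), `df` (n - 1), `p_value`
#'   and the 0.05 conclusion.
#' @examples
#' one_sample_t(seasonal_average(divandarreh_wells(), "nitrate"),
#'              mu0 = 50, alternative = "less")
#' @export
one_sample_t <- function(values, mu0,
                         alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("one-sample t test needs at least 2 values")
  if (stats::sd(values) == 0)
    stop("one-sample t test is undefined for a constant series (sd = 0)")
  ht <- stats::t.test(values, mu = mu0,
                      alternative = sub("_sided", ".sided", alternative))
  new_test_result(sprintf("One-sample t test vs %g mg/L (%s)", mu0,
                          alternative),
                  ht$statistic, ht$p.value, ht$parameter)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the series against a normal distribution with
#' the series' own estimated mean and standard deviation (the Lilliefors
#' setup). Because the null parameters are estimated from the data, the
#' classical KS p-value is conservative; the result carries that caveat.
#'
#' @param values Numeric series; `NA` dropped; needs n >= 5 and sd > 0.
#' @return A `nitrorisk_test` with the D statistic and approximate p-value.
#' @export
ks_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) stop("normality check needs at least 5 values")
  if (stats::sd(values) == 0)
    stop("normality check is undefined for a constant series (sd = 0)")
  ht <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  new_test_result("Kolmogorov-Smirnov normality check (estimated parameters)",
                  ht$statistic, ht$p.value,
                  note = paste("null parameters estimated from the data;",
                               "the classical KS p-value is conservative"))
}

#' Pearson correlation between two concentration series
#'
#' Pearson's r over complete pairs (rows where both series are resolved),
#' with the two-sided p-value from the t transform on n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric series of equal length (mg/L); pairs with any `NA`
#'   are dropped; at least 3 complete pairs required.
#' @return A `nitrorisk_test` whose `estimate` is r.
#' @examples
#' w <- divandarreh_wells()
#' pearson_cor(seasonal_average(w, "nitrate"), seasonal_average(w, "nitrite"))
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("Pearson correlation needs at least 3 complete pairs")
  ht <- stats::cor.test(x[ok], y[ok], method = "pearson")
  new_test_result(sprintf("Pearson correlation (n = %d complete pairs)",
                          sum(ok)),
                  ht$statistic, ht$p.value, ht$parameter,
                  estimate = unname(ht$estimate))
}

#' Ratio of the means of two series
#'
#' @param x,y Numeric series (mg/L); `NA` dropped independently.
#' @return `mean(x) / mean(y)`, dimensionless; errors when `mean(y)` is not
#'   strictly positive.
#' @export
ratio_of_means <- function(x, y) {
  mx <- mean(x, na.rm = TRUE)
  my <- mean(y, na.rm = TRUE)
  if (!is.finite(my) || my <= 0)
    stop("denominator series must have a strictly positive mean")
  mx / my
}
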