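#' Assess non-carcinogenic drinking-water risk for a well field
#'
#' The package's central interface: takes a [well_table()] and produces, for
#' each cohort, (i) the deterministic target hazard quotient per analyte at
#' a chosen concentration statistic, the hazard index TTHQ and its
#' classification against the threshold of 1; (ii) a seeded Monte Carlo
#' simulation of the same model with concentration uncertainty described by
#' the empirical bootstrap of the per-well seasonal averages, whose
#' 95th percentile is the conventional "reasonable worst case"; and (iii)
#' per-well THQs from the seasonal averages.
#'
#' The same seed is used for every cohort (common random numbers), so
#' cohort differences in the Monte Carlo tables reflect exposure factors
#' only, not sampling noise. The fit is fully reproducible from
#' `(table, arguments, seed)`.
#'
#' @param x A [well_table()].
#' @param cohorts Character vector of cohorts to assess (subset of
#'   `c("adult", "child")`).
#' @param nd_policy ND policy used to resolve censored observations before
#'   averaging (see [nd_policies()]); `half_lod` is the usual choice for
#'   risk modelling, `exclude` for descriptive work.
#' @param conc_stat Concentration statistic fed to the deterministic model:
#'   `"mean"` (default) or `"p95"` of the per-well seasonal averages.
#' @param mcs An [mcs_config()]; set `n_iterations = 0` is not supported —
#'   pass `run_simulation = FALSE` to skip the Monte Carlo stage.
#' @param seed Integer seed; overrides `mcs$seed` when given.
#' @param exposure Optional named list of lists
#'   (`exposure[[cohort]][[analyte]]` = [exposure_params()]) overriding the
#'   standard values from [default_exposure_params()].
#' @param run_simulation Run the Monte Carlo stage? Default `TRUE`.
#' @return An object of class `risk_assessment` with components
#'   `deterministic` (per-cohort THQ/TTHQ/classification), `mcs`
#'   (per-cohort `mcs_result` or `NULL`), `per_well` (data frame of
#'   per-well averages and THQs), plus the inputs echoed. Has `print`,
#'   `summary`, `plot` and `simulate` methods.
#' @examples
#' fit <- risk_assessment(divandarreh_wells(), seed = 1,
#'                        mcs = mcs_config(n_iterations = 2000))
#' fit
#' @export
risk_assessment <- function(x, cohorts = c("adult", "child"),
                            nd_policy = "exclude",
                            conc_stat = c("mean", "p95"),
                            mcs = mcs_config(), seed = NULL,
                            exposure = NULL, run_simulation = TRUE) {
  validate_well_table(x)
  cohorts <- match.arg(cohorts, several.ok = TRUE)
  conc_stat <- match.arg(conc_stat)
  if (!is.null(seed)) mcs$seed <- seed

  avgs <- lapply(stats::setNames(ANALYTES, ANALYTES), function(a)
    seasonal_average(x, a, policy = nd_policy))
  conc_point <- vapply(avgs, function(v) {
    v <- v[!is.na(v)]
    if (conc_stat == "mean") mean(v) else percentile(v, 95)
  }, numeric(1))

  get_params <- function(cohort) {
    lapply(stats::setNames(ANALYTES, ANALYTES), function(a)
      exposure[[cohort]][[a]] %||% default_exposure_params(cohort, a))
  }

  det <- lapply(stats::setNames(cohorts, cohorts), function(co) {
    p <- get_params(co)
    q <- vapply(ANALYTES, function(a) thq(conc_point[[a]], p[[a]]),
                numeric(1))
    tot <- tthq(q)
    list(thq = q, tthq = tot, classification = classify_risk(tot))
  })

  sim <- NULL
  if (run_simulation) {
    specs <- lapply(avgs, function(v) dist_bootstrap(v[!is.na(v)]))
    sim <- lapply(stats::setNames(cohorts, cohorts), function(co)
      run_mcs(specs, get_params(co), config = mcs))
  }

  per_well <- data.frame(name = x$name, stringsAsFactors = FALSE)
  for (a in ANALYTES) per_well[[paste0(a, "_average")]] <- unname(avgs[[a]])
  for (co in cohorts) {
    p <- get_params(co)
    for (a in ANALYTES)
      per_well[[paste0("thq_", a, "_", co)]] <-
        thq(ifelse(is.na(per_well[[paste0(a, "_average")]]), NA,
                   per_well[[paste0(a, "_average")]]), p[[a]])
    per_well[[paste0("tthq_", co)]] <-
      rowSums(per_well[paste0("thq_", ANALYTES, "_", co)])
  }

  structure(list(deterministic = det, mcs = sim, per_well = per_well,
                 conc_stat = conc_stat, conc_point = conc_point,
                 nd_policy = nd_policy, cohorts = cohorts,
                 seed = mcs$seed, n_wells = nrow(x),
                 provenance = attr(x, "provenance")),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, digits = 2, ...) {
  cat("Non-carcinogenic drinking-water risk assessment\n")
  cat("  wells: ", x$n_wells, " (", x$provenance, ")\n", sep = "")
  cat("  ND policy: ", x$nd_policy, "; concentration statistic: ",
      x$conc_stat, "\n", sep = "")
  for (co in x$cohorts) {
    d <- x$deterministic[[co]]
    cat(sprintf("  %s: THQ %s; TTHQ %s (%s)",
                co,
                paste(names(d$thq), round_half_away(d$thq, digits),
                      sep = " = ", collapse = ", "),
                round_half_away(d$tthq, digits), d$classification))
    if (!is.null(x$mcs))
      cat(sprintf("; MCS p95 TTHQ %s",
                  round_half_away(x$mcs[[co]]$tthq[["p95"]], digits)))
    cat("\n")
  }
  invisible(x)
}

#' @describeIn risk_assessment Detailed summary including the Monte Carlo
#'   percentile tables and convergence diagnostics.
#' @param object A `risk_assessment`.
#' @param ... Unused.
#' @export
summary.risk_assessment <- function(object, ...) {
  structure(object, class = c("summary.risk_assessment",
                              class(object)))
}

#' @export
print.summary.risk_assessment <- function(x, ...) {
  NextMethod()
  cat("Point concentrations fed to the deterministic model (mg/L):\n")
  print(round(x$conc_point, 4))
  if (!is.null(x$mcs)) for (co in x$cohorts) {
    cat("--", co, "cohort --\n")
    print(x$mcs[[co]])
  }
  invisible(x)
}

#' @describeIn risk_assessment Grouped bar chart of the deterministic THQs
#'   with the Monte Carlo 95th percentile marked per cohort.
#' @export
plot.risk_assessment <- function(x, ...) {
  det <- vapply(x$cohorts, function(co) x$deterministic[[co]]$thq,
                numeric(length(ANALYTES)))
  bp <- graphics::barplot(det, beside = TRUE, names.arg = x$cohorts,
                          legend.text = ANALYTES,
                          ylab = "target hazard quotient",
                          main = "THQ by cohort and analyte",
                          ylim = c(0, max(det, 1.2,
                                          if (!is.null(x$mcs))
                                            vapply(x$cohorts, function(co)
                                              x$mcs[[co]]$tthq[["p95"]],
                                              numeric(1))) * 1.1),
                          ...)
  graphics::abline(h = 1, lty = 2)
  if (!is.null(x$mcs))
    graphics::points(colMeans(bp),
                     vapply(x$cohorts, function(co)
                       x$mcs[[co]]$tthq[["p95"]], numeric(1)),
                     pch = 8)
  invisible(x)
}

#' @describeIn risk_assessment Draw `nsim` fresh Monte Carlo TTHQ samples
#'   per cohort (columns `<cohort>_<i>`), each of the fitted iteration
#'   count, using seeds derived from `seed`.
#' @param nsim Number of simulation replicates.
#' @param seed Seed for the replicate draws.
#' @export
simulate.risk_assessment <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$mcs))
    stop("the assessment was fitted with run_simulation = FALSE")
  cfg0 <- mcs_config(n_iterations = object$mcs[[1L]]$n_iterations)
  out <- list()
  for (i in seq_len(nsim)) {
    for (co in object$cohorts) {
      cfg <- cfg0
      if (!is.null(seed)) cfg$seed <- seed + (i - 1L)
      res <- run_mcs(
        conc = lapply(stats::setNames(ANALYTES, ANALYTES), function(a)
          dist_bootstrap(object$per_well[[paste0(a, "_average")]])),
        params = lapply(stats::setNames(ANALYTES, ANALYTES), function(a)
          default_exposure_params(co, a)),
        config = cfg)
      out[[paste0(co, "_", i)]] <- rowSums(res$draws)
    }
  }
  as.data.frame(out)
}
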