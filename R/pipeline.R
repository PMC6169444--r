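#' Pipeline configuration
#'
#' Describes one end-to-end run: where the well table comes from (a CSV
#' path or a [synthetic_config()] — exactly one), the ND policy, the
#' standard limits, the cohorts, the Monte Carlo settings, and where the
#' report bundle is written.
#'
#' @param input Path to a well-table CSV, or `NULL`.
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param nd_policy ND policy for the descriptive stages (see
#'   [nd_policies()]).
#' @param limits Named standard limits (mg/L) per analyte.
#' @param cohorts Cohorts to assess.
#' @param mcs An [mcs_config()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed applied to every stochastic stage.
#' @param verbose Narrate stages to the console?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            nd_policy = "exclude",
                            limits = default_limits(),
                            cohorts = c("adult", "child"),
                            mcs = mcs_config(), out_dir = tempfile("report_"),
                            seed = NULL, verbose = FALSE) {
  if (is.null(input) == is.null(synthetic))
    stop("exactly one of 'input' and 'synthetic' must be given")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  nd_policy <- match.arg(nd_policy, nd_policies())
  structure(list(input = input, synthetic = synthetic,
                 nd_policy = nd_policy, limits = limits, cohorts = cohorts,
                 mcs = mcs, out_dir = out_dir, seed = seed,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

stage <- function(name, expr, verbose = FALSE) {
  if (verbose) message("[", name, "] running")
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

report_round <- function(x, digits = 2) {
  if (is.list(x)) lapply(x, report_round, digits = digits)
  else if (is.numeric(x)) round_half_away(x, digits)
  else x
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest (CSV or synthetic generation), descriptive
#' statistics, exceedance screening, hypothesis tests, deterministic
#' THQ/TTHQ and the Monte Carlo simulation, and writes a machine-readable
#' bundle to `cfg$out_dir`:
#' \describe{
#'   \item{report.json}{summary statistics (raw and report-rounded to 2
#'     decimals, half away from zero), exceedance blocks, test blocks, and
#'     the per-cohort risk section with Monte Carlo percentile tables;}
#'   \item{wells.csv}{per-well seasonal averages and THQ/TTHQ columns;}
#'   \item{manifest.json}{seed, configuration echo, package and R versions,
#'     and the input file's MD5 — sufficient to reproduce the bundle
#'     bit-for-bit.}
#' }
#' Any stage failure removes partial outputs and raises an error whose
#' message is tagged with the failing stage.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the fit (`assessment`), the `report`
#'   list, and the output `paths`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(synthetic = synthetic_config(n_wells = 20),
#'                        seed = 1, mcs = mcs_config(n_iterations = 500))
#' out <- run_pipeline(cfg)
#' names(out$report)
#' }
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  paths <- file.path(cfg$out_dir,
                     c(report = "report.json", wells = "wells.csv",
                       manifest = "manifest.json"))
  names(paths) <- c("report", "wells", "manifest")
  on_fail <- function() unlink(paths[file.exists(paths)])

  tryCatch({
    wells <- stage("water_data", {
      if (!is.null(cfg$input)) read_well_table(cfg$input)
      else {
        syn <- cfg$synthetic
        if (!is.null(cfg$seed)) syn$seed <- cfg$seed
        generate_wells(syn)
      }
    }, cfg$verbose)

    avgs <- lapply(stats::setNames(ANALYTES, ANALYTES), function(a)
      seasonal_average(wells, a, policy = cfg$nd_policy))

    stats_block <- stage("summary_stats", lapply(avgs, function(v) {
      s <- summarize_conc(v)
      list(raw = unclass(s), rounded = report_round(unclass(s)))
    }), cfg$verbose)

    exceed_block <- stage("summary_stats", lapply(
      stats::setNames(ANALYTES, ANALYTES), function(a)
        unclass(exceedance(wells, a, limit = cfg$limits[[a]],
                           policy = cfg$nd_policy))), cfg$verbose)

    tests_block <- stage("summary_stats", {
      tl <- list()
      for (a in ANALYTES) {
        v <- avgs[[a]]
        tl[[paste0("ks_", a)]] <- unclass(ks_normality(v))
        tl[[paste0("t_", a, "_vs_limit")]] <-
          unclass(one_sample_t(v, mu0 = cfg$limits[[a]],
                               alternative = "less"))
      }
      tl$pearson_nitrate_nitrite <-
        unclass(pearson_cor(avgs$nitrate, avgs$nitrite))
      tl$ratio_nitrate_nitrite <-
        list(value = ratio_of_means(avgs$nitrate, avgs$nitrite),
             nd_policy = cfg$nd_policy)
      tl
    }, cfg$verbose)

    fit <- stage("risk", risk_assessment(
      wells, cohorts = cfg$cohorts, nd_policy = cfg$nd_policy,
      mcs = cfg$mcs, seed = cfg$seed), cfg$verbose)

    risk_block <- lapply(stats::setNames(cfg$cohorts, cfg$cohorts),
                         function(co) {
      d <- fit$deterministic[[co]]
      m <- fit$mcs[[co]]
      list(thq = as.list(d$thq), tthq = d$tthq,
           classification = d$classification,
           mcs = list(thq_percentiles = as.data.frame(m$thq),
                      tthq_percentiles = as.list(m$tthq),
                      mean_tthq = m$mean_tthq,
                      p95_ci_halfwidth = m$p95_ci_halfwidth,
                      n_iterations = m$n_iterations))
    })

    report <- list(provenance = attr(wells, "provenance"),
                   n_wells = nrow(wells), nd_policy = cfg$nd_policy,
                   limits = as.list(cfg$limits),
                   summary = stats_block, exceedance = exceed_block,
                   tests = tests_block, risk = risk_block)

    stage("report", {
      jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
      utils::write.csv(fit$per_well, paths[["wells"]], row.names = FALSE)
      manifest <- list(
        package = "nitrorisk",
        version = as.character(utils::packageVersion("nitrorisk")),
        r_version = as.character(getRversion()),
        seed = cfg$seed, nd_policy = cfg$nd_policy,
        limits = as.list(cfg$limits), cohorts = cfg$cohorts,
        mcs = list(n_iterations = cfg$mcs$n_iterations,
                   percentiles = cfg$mcs$percentiles),
        input = if (!is.null(cfg$input)) list(
          path = cfg$input,
          md5 = unname(tools::md5sum(cfg$input))) else NULL,
        synthetic = if (!is.null(cfg$synthetic))
          cfg$synthetic[c("n_wells", "nitrate", "nitrite",
                          "season_effect", "censor_below_lod")] else NULL)
      jsonlite::write_json(manifest, paths[["manifest"]],
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
    }, cfg$verbose)

    invisible(list(assessment = fit, report = report, paths = paths))
  }, error = function(e) { on_fail(); stop(e) })
}
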