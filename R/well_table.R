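ANALYTES <- c("nitrate", "nitrite")
SEASONS <- c("spring", "autumn")

#' Default analytical detection limits
#'
#' Limits of detection of the cadmium-reduction (nitrate) and diazotization
#' (nitrite) colorimetric methods, in mg/L. Concentrations below these cannot
#' be quantified and are recorded as non-detects ("ND").
#'
#' @return Named numeric vector with elements `nitrate` and `nitrite` (mg/L).
#' @export
default_lods <- function() c(nitrate = 0.3, nitrite = 0.05)

#' Non-detect substitution policies
#'
#' A left-censored observation ("ND", below the limit of detection) has no
#' numeric value; downstream statistics need a rule for it:
#' \describe{
#'   \item{exclude}{drop the observation (the default for descriptive
#'     statistics; reproduces per-well seasonal averages in which an ND
#'     season simply does not contribute)}
#'   \item{zero}{substitute 0 mg/L}
#'   \item{half_lod}{substitute LOD/2, the classical simple substitution}
#'   \item{lod}{substitute the LOD itself (an upper bound)}
#' }
#'
#' @return Character vector of the four policy names.
#' @export
nd_policies <- function() c("exclude", "zero", "half_lod", "lod")

#' Column dialect for well-table CSV files
#'
#' Maps the logical columns of a well table (locality name, projected
#' coordinates, and one concentration column per analyte and season) onto the
#' header names actually present in a CSV file.
#'
#' @param name,easting,northing Header names of the identifier columns.
#' @param nitrate_spring,nitrate_autumn,nitrite_spring,nitrite_autumn Header
#'   names of the concentration columns (mg/L; "ND" marks non-detects).
#' @param nd_token Token (case-insensitive, default `"ND"`) marking a
#'   censored cell.
#' @return A named list of class `well_dialect`.
#' @export
well_dialect <- function(name = "name", easting = "easting",
                         northing = "northing",
                         nitrate_spring = "nitrate_spring",
                         nitrate_autumn = "nitrate_autumn",
                         nitrite_spring = "nitrite_spring",
                         nitrite_autumn = "nitrite_autumn",
                         nd_token = "ND") {
  structure(list(name = name, easting = easting, northing = northing,
                 nitrate_spring = nitrate_spring,
                 nitrate_autumn = nitrate_autumn,
                 nitrite_spring = nitrite_spring,
                 nitrite_autumn = nitrite_autumn,
                 nd_token = nd_token),
            class = "well_dialect")
}

conc_cols <- function() {
  as.vector(outer(ANALYTES, SEASONS, paste, sep = "_"))
}

#' Construct a well table
#'
#' A `well_table` is a data frame with one row per locality (well) and, for
#' each analyte (`nitrate`, `nitrite`) and season (`spring`, `autumn`), a
#' numeric concentration column in mg/L plus a logical censoring column
#' (`*_cens`, `TRUE` for non-detects; the numeric value is then `NA`).
#'
#' @param df Data frame with columns `name`, `easting`, `northing`, the four
#'   concentration columns, and (optionally) the four `*_cens` columns;
#'   missing censoring columns are assumed all-`FALSE`.
#' @param lods Named numeric vector of detection limits per analyte (mg/L).
#' @param provenance Free-text label recording where the table came from.
#' @return An object of class `well_table` (also a `data.frame`).
#' @seealso [read_well_table()], [generate_wells()]
#' @export
well_table <- function(df, lods = default_lods(), provenance = "unspecified") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cc in conc_cols()) {
    cens <- paste0(cc, "_cens")
    if (is.null(df[[cens]])) df[[cens]] <- rep(FALSE, nrow(df))
  }
  out <- structure(df, lods = lods, provenance = provenance,
                   class = c("well_table", "data.frame"))
  validate_well_table(out)
  out
}

#' Validate a well table
#'
#' Checks the structural invariants: non-empty unique locality names, all
#' four (analyte, season) observation slots present, values non-negative,
#' value-present XOR censored, and strictly positive detection limits.
#'
#' @param x A `well_table`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_well_table <- function(x) {
  stopifnot(inherits(x, "well_table"))
  if (nrow(x) < 1L) stop("well table must contain at least one record")
  if (!all(c("name", "easting", "northing") %in% names(x)))
    stop("well table must have 'name', 'easting' and 'northing' columns")
  if (any(is.na(x$name) | !nzchar(x$name)))
    stop("locality names must be non-empty")
  if (anyDuplicated(x$name))
    stop("duplicate locality name: ", x$name[duplicated(x$name)][1L])
  lods <- attr(x, "lods")
  if (!all(ANALYTES %in% names(lods)) || any(lods[ANALYTES] <= 0))
    stop("detection limits must be positive and named for every analyte")
  for (cc in conc_cols()) {
    cens <- paste0(cc, "_cens")
    if (is.null(x[[cc]]) || is.null(x[[cens]]))
      stop("missing observation column: ", cc)
    v <- x[[cc]]
    f <- x[[cens]]
    if (any(f & !is.na(v)))
      stop("censored cells must carry no numeric value (", cc, ")")
    if (any(!f & is.na(v)))
      stop("uncensored cells must carry a value (", cc, ")")
    if (any(v < 0, na.rm = TRUE))
      stop("negative concentration in ", cc, " at row ",
           which(!is.na(v) & v < 0)[1L])
  }
  invisible(x)
}

#' Read a well-concentration table from CSV
#'
#' Reads one row per locality with per-season nitrate and nitrite
#' concentrations in mg/L. Cells equal to the dialect's ND token
#' (case-insensitive) become censored observations carrying the analyte's
#' detection limit; all other cells must parse as non-negative numbers with a
#' plain decimal point (thousands separators are rejected).
#'
#' @param path Path to the CSV file.
#' @param dialect A [well_dialect()] mapping logical columns to CSV headers.
#' @param lods Named detection limits per analyte (mg/L), attached to
#'   censored observations.
#' @param provenance Source label stored on the table; defaults to the file
#'   name.
#' @return A [well_table()].
#' @examples
#' wells <- read_well_table(
#'   system.file("extdata", "divandarreh_wells.csv", package = "nitrorisk"))
#' nrow(wells)
#' @export
read_well_table <- function(path, dialect = well_dialect(),
                            lods = default_lods(), provenance = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("input file contains no records: ", path)
  needed <- unlist(dialect[setdiff(names(dialect), "nd_token")])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("configured column(s) not found in header: ",
         paste(missing_cols, collapse = ", "))

  parse_num <- function(s, col) {
    s <- trimws(s)
    bad <- grepl(",", s, fixed = TRUE)
    if (any(bad))
      stop("thousands separators are not accepted (column ", col,
           ", row ", which(bad)[1L], ")")
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v))
      stop("unparseable value in column ", col, ", row ", which(is.na(v))[1L])
    v
  }

  df <- data.frame(name = trimws(raw[[dialect$name]]),
                   easting = parse_num(raw[[dialect$easting]], "easting"),
                   northing = parse_num(raw[[dialect$northing]], "northing"),
                   stringsAsFactors = FALSE)
  for (a in ANALYTES) {
    for (s in SEASONS) {
      cc <- paste(a, s, sep = "_")
      cells <- trimws(raw[[dialect[[cc]]]])
      cens <- toupper(cells) == toupper(dialect$nd_token)
      val <- rep(NA_real_, length(cells))
      if (any(!cens)) val[!cens] <- parse_num(cells[!cens], cc)
      neg <- which(!is.na(val) & val < 0)
      if (length(neg))
        stop("negative concentration in ", cc, " at row ", neg[1L],
             " (", df$name[neg[1L]], ")")
      df[[cc]] <- val
      df[[paste0(cc, "_cens")]] <- cens
    }
  }
  well_table(df, lods = lods,
             provenance = provenance %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a well table to CSV
#'
#' Writes the table back in the standard column layout, with censored cells
#' emitted as the ND token, so that [read_well_table()] round-trips the data
#' exactly. With `normalized = TRUE` a per-analyte seasonal-average column
#' (under the given ND policy) and a per-row censoring count are appended.
#'
#' @param x A [well_table()].
#' @param path Output CSV path.
#' @param normalized Append `*_average` and `n_censored` columns?
#' @param policy ND policy used for the appended averages.
#' @param nd_token Token written for censored cells.
#' @return `path`, invisibly.
#' @export
write_well_table <- function(x, path, normalized = FALSE,
                             policy = "exclude", nd_token = "ND") {
  validate_well_table(x)
  out <- data.frame(name = x$name, easting = x$easting,
                    northing = x$northing, stringsAsFactors = FALSE)
  fmt <- function(v) ifelse(is.na(v), nd_token, format(v, trim = TRUE,
                                                       scientific = FALSE))
  for (cc in conc_cols()) out[[cc]] <- fmt(x[[cc]])
  if (normalized) {
    for (a in ANALYTES) {
      avg <- seasonal_average(x, a, policy = policy)
      out[[paste0(a, "_average")]] <- ifelse(is.na(avg), nd_token,
                                             format(avg, trim = TRUE))
    }
    cens_cols <- paste0(conc_cols(), "_cens")
    out$n_censored <- rowSums(as.data.frame(x)[cens_cols])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Resolve censored observations under an ND policy
#'
#' Applies a substitution policy to a vector of observations: detected values
#' pass through unchanged; non-detects become `NA` (`exclude`), `0` (`zero`),
#' `lod / 2` (`half_lod`) or `lod` (`lod`).
#'
#' @param value Numeric concentrations in mg/L (`NA` where censored).
#' @param censored Logical, `TRUE` for non-detects.
#' @param lod Detection limit(s) in mg/L, recycled along `value`.
#' @param policy One of [nd_policies()].
#' @return Numeric vector of resolved concentrations (`NA` = excluded).
#' @examples
#' resolve_nd(c(5.6, NA), c(FALSE, TRUE), lod = 0.05, policy = "half_lod")
#' @export
resolve_nd <- function(value, censored, lod, policy = "exclude") {
  policy <- match.arg(policy, nd_policies())
  stopifnot(length(value) == length(censored))
  sub <- switch(policy,
                exclude = NA_real_,
                zero = 0,
                half_lod = lod / 2,
                lod = lod)
  out <- value
  out[censored] <- rep_len(sub, length(value))[censored]
  out
}

resolve_column <- function(x, analyte, season, policy) {
  cc <- paste(analyte, season, sep = "_")
  resolve_nd(x[[cc]], x[[paste0(cc, "_cens")]],
             lod = attr(x, "lods")[[analyte]], policy = policy)
}

#' Per-well seasonal average concentration
#'
#' Arithmetic mean of the resolved spring and autumn concentrations for one
#' analyte. If one season is unresolvable (censored under `exclude`), the
#' other season's value is returned alone; if both are, the result is `NA`.
#'
#' @param x A [well_table()].
#' @param analyte `"nitrate"` or `"nitrite"`.
#' @param policy ND policy, see [nd_policies()].
#' @return Numeric vector of seasonal means (mg/L), one per well, named by
#'   locality.
#' @examples
#' wells <- read_well_table(
#'   system.file("extdata", "divandarreh_wells.csv", package = "nitrorisk"))
#' head(seasonal_average(wells, "nitrate"))
#' @export
seasonal_average <- function(x, analyte = ANALYTES, policy = "exclude") {
  analyte <- match.arg(analyte)
  validate_well_table(x)
  m <- cbind(resolve_column(x, analyte, "spring", policy),
             resolve_column(x, analyte, "autumn", policy))
  avg <- rowMeans(m, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  stats::setNames(avg, x$name)
}

#' @export
print.well_table <- function(x, ...) {
  cat("Well-concentration table: ", nrow(x), " localities (",
      attr(x, "provenance"), ")\n", sep = "")
  cens <- sum(vapply(paste0(conc_cols(), "_cens"),
                     function(cc) sum(x[[cc]]), integer(1)))
  cat("  analytes: ", paste(ANALYTES, collapse = ", "),
      "; seasons: ", paste(SEASONS, collapse = ", "),
      "; censored cells: ", cens, "\n", sep = "")
  lods <- attr(x, "lods")
  cat("  LOD (mg/L): ", paste(names(lods), lods, sep = " = ",
                              collapse = ", "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("  ... and", nrow(x) - 5L, "more rows\n")
  invisible(x)
}

#' Packaged two-season well survey of rural Divandarreh County
#'
#' Loads the packaged fixture: nitrate and nitrite concentrations (mg/L)
#' measured in spring and autumn 2016 in rural drinking-water wells of
#' Divandarreh County, Kurdistan province, Iran. The source table prints 58
#' localities although the survey text counts 59 active wells; the table is
#' shipped as printed and the discrepancy is recorded in the provenance
#' label, not repaired. Non-detects ("ND") appear for nitrite in three
#' localities.
#'
#' @return A [well_table()] with 58 records.
#' @examples
#' wells <- divandarreh_wells()
#' summarize_conc(seasonal_average(wells, "nitrate"))
#' @export
divandarreh_wells <- function() {
  path <- system.file("extdata", "divandarreh_wells.csv",
                      package = "nitrorisk", mustWork = TRUE)
  read_well_table(path, provenance = paste(
    "Divandarreh County rural well survey, spring/autumn 2016;",
    "58 localities as printed (survey text counts 59 active wells)"))
}
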