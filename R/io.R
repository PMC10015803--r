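#' Read a personal measurement table into an ExposureExperiment
#'
#' Reads an RFC-4180 CSV with one row per (salon, worker, chemical)
#' observation and builds the campaign container. The \code{concentration}
#' column admits numeric values (ug/m3 toluene equivalents) or the token
#' \code{"<RL"} for a below-reporting-limit report. Reporting limits are
#' enforced here, at ingest: a numeric value strictly below the
#' class-appropriate limit is moved to the censored set (with a warning), so
#' every downstream stage sees one canonical censored dataset.
#'
#' @param path CSV file with header columns \code{salon_id}, \code{worker_id},
#'   \code{duration_min}, \code{chemical}, \code{cas}, \code{chem_class},
#'   \code{concentration} and optionally \code{tvoc_included}.
#' @param limits a [ReportingLimits-class] object.
#' @return An [ExposureExperiment-class]; zero samples for a header-only file.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("salon_id,worker_id,duration_min,chemical,cas,chem_class,concentration",
#'              "s1,h1,176,formaldehyde,59-00-0,aldehyde,38"), f)
#' readMeasurements(f)
#' @export
readMeasurements <- function(path, limits = reportingLimits()) {
  stopifnot(is(limits, "ReportingLimits"))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("salon_id", "worker_id", "duration_min", "chemical", "cas",
                "chem_class", "concentration")
  missing_cols <- setdiff(required, colnames(raw))
  if (length(missing_cols))
    stop("measurement file format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"tvoc_included" %in% colnames(raw))
    raw$tvoc_included <- rep("TRUE", nrow(raw))

  if (nrow(raw) == 0L) {
    return(ExposureExperiment(
      concentration = matrix(numeric(0), 0, 0),
      chemicals = data.frame(name = character(0), cas = character(0),
                             chem_class = character(0),
                             tvoc_included = logical(0)),
      samples = data.frame(salon_id = character(0), worker_id = character(0),
                           duration_min = numeric(0)),
      reporting_limits = limits))
  }

  key <- paste(raw$salon_id, raw$worker_id, raw$chemical, sep = "\r")
  if (anyDuplicated(key)) {
    d <- raw[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate record for (%s, %s, %s)", d$salon_id, d$worker_id,
                 d$chemical), call. = FALSE)
  }

  conc_txt <- trimws(raw$concentration)
  is_rl <- conc_txt == "<RL"
  conc <- suppressWarnings(as.numeric(conc_txt))
  bad <- !is_rl & is.na(conc)
  if (any(bad))
    stop(sprintf("parse error: non-numeric concentration '%s' at row %d",
                 conc_txt[which(bad)[1L]], which(bad)[1L]), call. = FALSE)
  if (!all(raw$chem_class %in% .CHEM_CLASSES))
    stop("chem_class must be 'VOC' or 'aldehyde'", call. = FALSE)

  rl <- ifelse(raw$chem_class == "aldehyde", limits@aldehyde_limit,
               limits@voc_limit)
  below <- !is_rl & conc < rl
  if (any(below)) {
    warning(sprintf(
      "%d concentration(s) below the reporting limit moved to the censored set (e.g. %s at %s ug/m3 < %s)",
      sum(below), raw$chemical[which(below)[1L]], conc_txt[which(below)[1L]],
      rl[which(below)[1L]]), call. = FALSE)
  }
  censored_row <- is_rl | below
  conc[censored_row] <- NA_real_

  chem_key <- paste(raw$chemical, raw$cas, sep = "\r")
  chemicals <- raw[!duplicated(chem_key),
                   c("chemical", "cas", "chem_class", "tvoc_included")]
  names(chemicals)[1L] <- "name"
  chemicals$tvoc_included <- toupper(trimws(chemicals$tvoc_included)) %in%
    c("TRUE", "T", "1", "YES")
  samp_key <- paste(raw$salon_id, raw$worker_id, sep = "\r")
  samples <- raw[!duplicated(samp_key),
                 c("salon_id", "worker_id", "duration_min")]
  samples$duration_min <- as.numeric(samples$duration_min)

  i <- match(chem_key, chem_key[!duplicated(chem_key)])
  j <- match(samp_key, samp_key[!duplicated(samp_key)])
  conc_mat <- matrix(NA_real_, nrow(chemicals), nrow(samples))
  cen_mat <- matrix(FALSE, nrow(chemicals), nrow(samples))
  conc_mat[cbind(i, j)] <- conc
  cen_mat[cbind(i, j)] <- censored_row

  ExposureExperiment(concentration = conc_mat, censored = cen_mat,
                     chemicals = chemicals, samples = samples,
                     reporting_limits = limits)
}

#' Read a reference-value / OEL registry
#'
#' @param path CSV with columns \code{chemical}, \code{cas}, \code{rv},
#'   \code{oel_se}, \code{oel_nordic}, \code{oel_intl} (blank cells mark an
#'   absent tier; a tier cell may hold several ";"-separated candidate
#'   values), plus optional \code{*_source} authority labels.
#' @return A [ReferenceRegistry-class].
#' @seealso [table3Registry()] for the packaged fixture registry.
#' @export
readRegistry <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  unknown <- setdiff(colnames(raw), .REGISTRY_COLS)
  if (length(unknown))
    stop("registry format error: unknown column(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing_cols <- setdiff(c("chemical", "cas"), colnames(raw))
  if (length(missing_cols))
    stop("registry format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ReferenceRegistry(raw)
}

#' The packaged registry of reference values and OELs
#'
#' Loads the fixture registry shipped with the package, covering the selection
#' of VOCs and aldehydes with significant exposure contributions in a Swedish
#' hair-salon campaign: chronic reference values where available, and Swedish
#' / Nordic / international OELs otherwise. The formaldehyde CAS is stored as
#' published in the source table ("59-00-0") and is deliberately not corrected
#' to the standard registry number.
#'
#' @return A [ReferenceRegistry-class].
#' @examples
#' table3Registry()
#' @export
table3Registry <- function() {
  readRegistry(system.file("extdata", "table3_registry.csv",
                           package = "vocmix", mustWork = TRUE))
}

.formatFull <- function(x) {
  # full-precision serialization: 15 significant digits round-trips doubles
  # well past the 12-digit contract
  ifelse(is.na(x), "", trimws(formatC(x, digits = 15, format = "g")))
}

.formatDisplay <- function(x, sigfigs) {
  ifelse(is.na(x), "", as.character(signif(x, sigfigs)))
}

#' Write a risk report (and read it back)
#'
#' Writes a per-result CSV with TVOC, HI, maxHQ chemical and value, MCR, MCR
#' substance group, contribution count and risk flag. Numeric columns are
#' written twice: at full precision and as display values rounded to
#' \code{rounding_sigfigs_report} significant figures. A long-format
#' hazard-quotient breakdown (one row per contributing chemical per result) is
#' written alongside with suffix \code{"_hq.csv"}.
#'
#' @param results a [RiskAssessment-class] with at least one result.
#' @param path output CSV path.
#' @param config a [RunConfig-class]; controls display rounding.
#' @return Invisibly, a character vector of the two files written.
#' @export
writeReport <- function(results, path, config = runConfig()) {
  stopifnot(is(results, "RiskAssessment"))
  res <- riskResults(results)
  if (nrow(res) == 0L)
    stop("cannot write a report for an empty result set", call. = FALSE)
  grp <- classifyMCR(results, config)
  sig <- config@rounding_sigfigs_report
  out <- data.frame(
    scope = results@scope,
    id = res$id,
    salon_id = res$salon_id,
    tvoc = .formatFull(res$tvoc),
    hi = .formatFull(res$hi),
    max_hq_chemical = res$max_hq_chemical,
    max_hq = .formatFull(res$max_hq),
    mcr = .formatFull(res$mcr),
    n_contributing = res$n_contributing,
    mcr_group = grp$group,
    substances_of_concern = grp$substances_of_concern,
    risk_flag = res$risk_flag,
    tvoc_display = .formatDisplay(res$tvoc, sig),
    hi_display = .formatDisplay(res$hi, sig),
    max_hq_display = .formatDisplay(res$max_hq, sig),
    mcr_display = .formatDisplay(res$mcr, sig),
    check.names = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O error writing report to ", path, ": ", conditionMessage(ok),
         call. = FALSE)

  hq <- hqMatrix(results)
  idx <- which(!is.na(hq), arr.ind = TRUE)
  breakdown <- data.frame(
    id = res$id[idx[, 2L]],
    chemical = rownames(hq)[idx[, 1L]],
    hq = .formatFull(hq[idx]),
    hq_display = .formatDisplay(hq[idx], sig))
  breakdown <- breakdown[order(breakdown$id, -as.numeric(breakdown$hq)), ]
  hq_path <- paste0(tools::file_path_sans_ext(path), "_hq.csv")
  utils::write.csv(breakdown, hq_path, row.names = FALSE, quote = TRUE)
  invisible(c(path, hq_path))
}

#' @rdname writeReport
#' @param path path of a report written by \code{writeReport}.
#' @return \code{readReport}: the per-result table with full-precision numeric
#'   columns restored.
#' @export
readReport <- function(path) {
  out <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  for (col in c("tvoc", "hi", "max_hq", "mcr"))
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  out$n_contributing <- as.integer(out$n_contributing)
  out$risk_flag <- out$risk_flag == "TRUE"
  out
}

#' Read a flat key-value run configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments are
#' ignored. Recognised keys: \code{voc_limit}, \code{aldehyde_limit},
#' \code{risk_threshold}, \code{mcr_dominance_cutoff},
#' \code{rounding_sigfigs_report}. Missing keys keep their defaults.
#'
#' @param path configuration file path.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("config parse error at line: ", lines[which(bad)[1L]], call. = FALSE)
  vals <- stats::setNames(as.numeric(trimws(vapply(kv, `[`, "", 2L))),
                          trimws(vapply(kv, `[`, "", 1L)))
  pick <- function(key, default) if (key %in% names(vals)) vals[[key]] else default
  runConfig(
    reporting_limits = reportingLimits(pick("voc_limit", 3),
                                       pick("aldehyde_limit", 0.3)),
    risk_threshold = pick("risk_threshold", 1.0),
    mcr_dominance_cutoff = pick("mcr_dominance_cutoff", 2.0),
    rounding_sigfigs_report = pick("rounding_sigfigs_report", 1L))
}

#' Read an indoor-climate table
#'
#' One record per salon with CO2 (ppm), air temperature (deg C) and relative
#' humidity (percent). CO2 below 300 ppm is rejected as physically implausible
#' for occupied indoor spaces.
#'
#' @param path CSV with columns \code{salon_id}, \code{co2_ppm},
#'   \code{temp_c}, \code{rh_pct}.
#' @return A data.frame of climate records.
#' @export
readClimate <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  required <- c("salon_id", "co2_ppm", "temp_c", "rh_pct")
  missing_cols <- setdiff(required, colnames(raw))
  if (length(missing_cols))
    stop("climate file format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(raw$salon_id))
    stop("one climate record per salon expected", call. = FALSE)
  if (any(raw$co2_ppm <= 300))
    stop("co2_ppm must exceed 300 ppm", call. = FALSE)
  if (any(raw$rh_pct < 0 | raw$rh_pct > 100))
    stop("rh_pct must lie in [0, 100]", call. = FALSE)
  raw
}
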