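#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
NULL

#' Reporting limits for VOC and aldehyde quantification
#'
#' Analytical reporting limits below which a concentration is treated as
#' non-detected and excluded from TVOC and hazard-index calculations. The
#' defaults (3 ug/m3 for VOCs, 0.3 ug/m3 for aldehydes) correspond to
#' thermal-desorption GC-MS and DNPH/HPLC-UV workflows commonly used for
#' personal sampling of indoor air.
#'
#' @slot voc_limit numeric(1), reporting limit for VOCs in ug/m3.
#' @slot aldehyde_limit numeric(1), reporting limit for aldehydes in ug/m3.
#' @export
setClass("ReportingLimits",
  representation(voc_limit = "numeric", aldehyde_limit = "numeric"))

setValidity("ReportingLimits", function(object) {
  if (length(object@voc_limit) != 1L || !is.finite(object@voc_limit) ||
      object@voc_limit <= 0)
    return("voc_limit must be a single positive number")
  if (length(object@aldehyde_limit) != 1L || !is.finite(object@aldehyde_limit) ||
      object@aldehyde_limit <= 0)
    return("aldehyde_limit must be a single positive number")
  TRUE
})

#' @param voc_limit,aldehyde_limit positive reporting limits in ug/m3.
#' @return A \code{ReportingLimits} object.
#' @examples
#' reportingLimits()
#' reportingLimits(voc_limit = 5, aldehyde_limit = 0.5)
#' @rdname ReportingLimits-class
#' @export
reportingLimits <- function(voc_limit = 3, aldehyde_limit = 0.3) {
  new("ReportingLimits", voc_limit = as.numeric(voc_limit),
      aldehyde_limit = as.numeric(aldehyde_limit))
}

#' Run configuration for the risk pipeline
#'
#' Bundles the tunable thresholds of the pipeline: the reporting limits applied
#' at ingest, the hazard-index threshold at/above which risk is flagged, the
#' MCR cutoff separating one-substance-dominated from several-substance
#' mixtures, and the number of significant figures used for display columns in
#' written reports.
#'
#' @slot reporting_limits a [ReportingLimits-class] object.
#' @slot risk_threshold numeric(1); samples with HI at or above it are flagged.
#' @slot mcr_dominance_cutoff numeric(1); MCR below it means one substance
#'   dominates the combined effect.
#' @slot rounding_sigfigs_report integer(1); significant figures for report
#'   display columns (full precision is always retained alongside).
#' @export
setClass("RunConfig",
  representation(reporting_limits = "ReportingLimits",
                 risk_threshold = "numeric",
                 mcr_dominance_cutoff = "numeric",
                 rounding_sigfigs_report = "integer"))

setValidity("RunConfig", function(object) {
  if (length(object@risk_threshold) != 1L || object@risk_threshold <= 0)
    return("risk_threshold must be a single positive number")
  if (length(object@mcr_dominance_cutoff) != 1L ||
      object@mcr_dominance_cutoff <= 0)
    return("mcr_dominance_cutoff must be a single positive number")
  if (length(object@rounding_sigfigs_report) != 1L ||
      object@rounding_sigfigs_report < 1L)
    return("rounding_sigfigs_report must be a positive integer")
  TRUE
})

#' @param reporting_limits a [ReportingLimits-class] object.
#' @param risk_threshold HI threshold flagging potential non-cancer risk.
#' @param mcr_dominance_cutoff MCR cutoff between groups IIIA and IIIB.
#' @param rounding_sigfigs_report significant figures for display rounding.
#' @return A \code{RunConfig} object.
#' @examples
#' runConfig()
#' @rdname RunConfig-class
#' @export
runConfig <- function(reporting_limits = reportingLimits(),
                      risk_threshold = 1.0,
                      mcr_dominance_cutoff = 2.0,
                      rounding_sigfigs_report = 1L) {
  new("RunConfig", reporting_limits = reporting_limits,
      risk_threshold = as.numeric(risk_threshold),
      mcr_dominance_cutoff = as.numeric(mcr_dominance_cutoff),
      rounding_sigfigs_report = as.integer(rounding_sigfigs_report))
}

.CHEM_CLASSES <- c("VOC", "aldehyde")
.CAS_PATTERN <- "^[0-9]{2,7}-[0-9]{2}-[0-9]$"

.validCas <- function(cas) {
  # a cell may hold one CAS, a ";"-separated group, or the sentinel "NA"
  vapply(cas, function(x) {
    if (is.na(x) || identical(x, "NA")) return(TRUE)
    parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    length(parts) >= 1L && all(grepl(.CAS_PATTERN, parts))
  }, logical(1))
}

#' Container for a personal exposure measurement campaign
#'
#' An \code{ExposureExperiment} extends
#' \linkS4class{SummarizedExperiment}: rows are analytes (chemicals), columns
#' are worker-shift samples. Two assays are carried: \code{"concentration"}
#' (ug/m3 toluene equivalents; \code{NA} wherever the analyte was not
#' quantified) and \code{"censored"} (logical; \code{TRUE} where the analyte
#' was reported below the class-specific reporting limit and therefore carries
#' no numeric value). Row metadata holds the chemical identity (\code{name},
#' \code{cas}, \code{chem_class}, \code{tvoc_included}); column metadata holds
#' \code{salon_id}, \code{worker_id} and \code{duration_min}. The reporting
#' limits active at ingest are stored in \code{metadata(x)$reporting_limits}.
#'
#' Censored entries never contribute to TVOC or hazard-index computations;
#' enforcing the exclusion at ingest gives all downstream stages one canonical
#' censored dataset.
#'
#' @export
setClass("ExposureExperiment", contains = "SummarizedExperiment")

setValidity("ExposureExperiment", function(object) {
  msg <- character(0)
  an <- names(assays(object))
  if (!all(c("concentration", "censored") %in% an))
    return("assays must include 'concentration' and 'censored'")
  conc <- assay(object, "concentration")
  cen <- assay(object, "censored")
  if (!is.logical(cen))
    msg <- c(msg, "'censored' assay must be logical")
  if (any(!is.na(conc) & conc <= 0))
    msg <- c(msg, "all quantified concentrations must be > 0")
  if (any(cen & !is.na(conc), na.rm = TRUE))
    msg <- c(msg, "a censored analyte must not carry a numeric concentration")
  rd <- rowData(object)
  need_rd <- c("name", "cas", "chem_class", "tvoc_included")
  if (!all(need_rd %in% colnames(rd)))
    return(paste("rowData must contain:", paste(need_rd, collapse = ", ")))
  if (any(!nzchar(rd$name)))
    msg <- c(msg, "chemical names must be non-empty")
  if (!all(rd$chem_class %in% .CHEM_CLASSES))
    msg <- c(msg, "chem_class must be 'VOC' or 'aldehyde'")
  if (!all(.validCas(as.character(rd$cas))))
    msg <- c(msg, "cas must match the CAS pattern, a ';'-group of CAS, or 'NA'")
  if (anyDuplicated(paste(rd$name, rd$cas, sep = "\r")))
    msg <- c(msg, "chemicals must be unique by (name, cas)")
  cd <- colData(object)
  need_cd <- c("salon_id", "worker_id", "duration_min")
  if (!all(need_cd %in% colnames(cd)))
    return(paste("colData must contain:", paste(need_cd, collapse = ", ")))
  if (ncol(object) && any(!is.finite(cd$duration_min) | cd$duration_min <= 0))
    msg <- c(msg, "duration_min must be positive")
  if (anyDuplicated(paste(cd$salon_id, cd$worker_id, sep = "\r")))
    msg <- c(msg, "(salon_id, worker_id) must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an ExposureExperiment
#'
#' @param concentration numeric matrix, chemicals x samples, \code{NA} where
#'   not quantified.
#' @param censored logical matrix of the same dimension; \code{TRUE} marks a
#'   below-reporting-limit report. Defaults to all-\code{FALSE}.
#' @param chemicals data.frame/DataFrame with columns \code{name}, \code{cas},
#'   \code{chem_class} ("VOC" or "aldehyde") and \code{tvoc_included}.
#' @param samples data.frame/DataFrame with columns \code{salon_id},
#'   \code{worker_id}, \code{duration_min}.
#' @param reporting_limits a [ReportingLimits-class] object recorded in the
#'   object metadata.
#' @return An \code{ExposureExperiment}.
#' @examples
#' ee <- ExposureExperiment(
#'   concentration = matrix(c(38, NA), 2, 1,
#'     dimnames = list(c("formaldehyde", "limonene"), "s1:h1")),
#'   censored = matrix(c(FALSE, TRUE), 2, 1),
#'   chemicals = data.frame(name = c("formaldehyde", "limonene"),
#'     cas = c("59-00-0", "5989-27-5"),
#'     chem_class = c("aldehyde", "VOC"), tvoc_included = TRUE),
#'   samples = data.frame(salon_id = "s1", worker_id = "h1",
#'     duration_min = 176))
#' ee
#' @rdname ExposureExperiment-class
#' @export
ExposureExperiment <- function(concentration, censored = NULL,
                               chemicals, samples,
                               reporting_limits = reportingLimits()) {
  concentration <- as.matrix(concentration)
  if (is.null(censored))
    censored <- matrix(FALSE, nrow(concentration), ncol(concentration))
  censored <- matrix(as.logical(censored), nrow(concentration),
                     ncol(concentration))
  chemicals <- DataFrame(chemicals)
  samples <- DataFrame(samples)
  rownames(concentration) <- chemicals$name
  if (ncol(concentration) && !is.null(samples$salon_id))
    colnames(concentration) <- paste(samples$salon_id, samples$worker_id,
                                     sep = ":")
  dimnames(censored) <- dimnames(concentration)
  se <- SummarizedExperiment(
    assays = SimpleList(concentration = concentration, censored = censored),
    rowData = chemicals, colData = samples)
  metadata(se)$reporting_limits <- reporting_limits
  new("ExposureExperiment", se)
}

#' Registry of health-based reference values and occupational exposure limits
#'
#' One row per analyte, keyed primarily by CAS with a normalized-name
#' fallback. Four limit tiers are carried: the chronic reference value
#' (\code{rv}), the Swedish OEL (\code{oel_se}), Nordic OELs
#' (\code{oel_nordic}) and international OELs (\code{oel_intl}); the latter
#' two admit several ";"-separated candidate values from which the lowest is
#' chosen at resolution time. Companion \code{*_source} columns carry the
#' authority labels.
#'
#' @slot table a \code{DataFrame} with columns \code{chemical}, \code{cas},
#'   \code{rv}, \code{oel_se}, \code{oel_nordic}, \code{oel_intl} and the
#'   corresponding \code{*_source} labels.
#' @seealso [readRegistry()], [resolveReference()], [table3Registry()]
#' @export
setClass("ReferenceRegistry", representation(table = "DataFrame"))

.REGISTRY_COLS <- c("chemical", "cas", "rv", "rv_source", "oel_se",
                    "oel_se_source", "oel_nordic", "oel_nordic_source",
                    "oel_intl", "oel_intl_source")

.parseLimits <- function(x) {
  # ";"-separated positive numbers; NA/blank -> numeric(0)
  if (is.na(x) || !nzchar(trimws(x))) return(numeric(0))
  v <- suppressWarnings(as.numeric(trimws(strsplit(as.character(x), ";",
                                                   fixed = TRUE)[[1]])))
  if (anyNA(v)) stop("non-numeric limit value: ", x, call. = FALSE)
  v
}

setValidity("ReferenceRegistry", function(object) {
  tab <- object@table
  if (!all(.REGISTRY_COLS %in% colnames(tab)))
    return(paste("registry table must contain:",
                 paste(.REGISTRY_COLS, collapse = ", ")))
  for (col in c("rv", "oel_se", "oel_nordic", "oel_intl")) {
    vals <- unlist(lapply(as.character(tab[[col]]), .parseLimits))
    if (any(vals <= 0))
      return(sprintf("limit values in '%s' must be > 0", col))
  }
  TRUE
})

#' @rdname ReferenceRegistry-class
#' @param table registry table (see slot description).
#' @export
ReferenceRegistry <- function(table) {
  tab <- DataFrame(table)
  for (col in setdiff(.REGISTRY_COLS, colnames(tab)))
    tab[[col]] <- rep(NA_character_, nrow(tab))
  for (col in setdiff(colnames(tab), c("chemical", "cas")))
    tab[[col]] <- as.character(tab[[col]])
  new("ReferenceRegistry", table = tab[, .REGISTRY_COLS])
}

#' Per-sample (or per-salon) risk assessment results
#'
#' Holds, for one scope (worker-shift samples or salon aggregates), the full
#' hazard-quotient matrix together with the derived summary per result: TVOC,
#' hazard index (HI), the maximum hazard quotient and the chemical attaining
#' it, the maximum cumulative ratio (MCR = HI / maxHQ), the number of
#' chemicals contributing to HI, and the risk flag (HI at or above the
#' configured threshold).
#'
#' @slot scope "sample" or "salon".
#' @slot results a \code{DataFrame}, one row per sample/salon.
#' @slot hq numeric matrix of hazard quotients, chemicals x results; \code{NA}
#'   marks a non-contributing (censored, absent or unresolved) combination.
#' @slot tvoc_by_result numeric vector of TVOC (ug/m3) per result.
#' @slot unresolved character vector of detected chemicals that could not be
#'   resolved to any reference value or OEL (they contribute to TVOC, never
#'   to HI).
#' @slot config the [RunConfig-class] used.
#' @export
setClass("RiskAssessment",
  representation(scope = "character", results = "DataFrame", hq = "matrix",
                 tvoc_by_result = "numeric", unresolved = "character",
                 config = "RunConfig"))

setValidity("RiskAssessment", function(object) {
  if (!object@scope %in% c("sample", "salon"))
    return("scope must be 'sample' or 'salon'")
  if (nrow(object@results) != ncol(object@hq))
    return("results rows must match hq columns")
  hi <- object@results$hi
  chk <- colSums(object@hq, na.rm = TRUE)
  if (length(hi) && any(abs(hi - chk) > 1e-9 * pmax(1, abs(hi))))
    return("hi must equal the sum of hazard quotients (1e-9 relative)")
  TRUE
})

#' @describeIn RiskAssessment-class the per-result summary as a data.frame
#'   (id, salon_id, tvoc, hi, max_hq, max_hq_chemical, mcr, n_contributing,
#'   risk_flag).
#' @param x a \code{RiskAssessment}.
#' @export
riskResults <- function(x) {
  stopifnot(is(x, "RiskAssessment"))
  as.data.frame(x@results)
}

#' @describeIn RiskAssessment-class the chemicals x results hazard-quotient
#'   matrix.
#' @export
hqMatrix <- function(x) {
  stopifnot(is(x, "RiskAssessment"))
  x@hq
}

#' @describeIn RiskAssessment-class detected chemicals with no resolvable
#'   reference value or OEL.
#' @export
unresolvedChemicals <- function(x) {
  stopifnot(is(x, "RiskAssessment"))
  x@unresolved
}

setMethod("show", "ExposureExperiment", function(object) {
  cat(sprintf("ExposureExperiment: %d chemicals x %d worker-shift samples\n",
              nrow(object), ncol(object)))
  rl <- metadata(object)$reporting_limits
  if (is(rl, "ReportingLimits"))
    cat(sprintf("reporting limits: VOC %g, aldehyde %g ug/m3\n",
                rl@voc_limit, rl@aldehyde_limit))
  nq <- sum(!is.na(assay(object, "concentration")))
  nc <- sum(assay(object, "censored"))
  cat(sprintf("quantified entries: %d; censored (<RL): %d\n", nq, nc))
  invisible(NULL)
})

setMethod("show", "ReferenceRegistry", function(object) {
  tab <- object@table
  n <- nrow(tab)
  has <- function(col) sum(vapply(as.character(tab[[col]]),
    function(x) length(.parseLimits(x)) > 0, logical(1)))
  cat(sprintf("ReferenceRegistry: %d chemicals (RV %d, OEL[SE] %d, OEL[Nordic] %d, OEL[intl] %d)\n",
              n, has("rv"), has("oel_se"), has("oel_nordic"), has("oel_intl")))
  invisible(NULL)
})

setMethod("show", "RiskAssessment", function(object) {
  res <- object@results
  cat(sprintf("RiskAssessment (%s scope): %d results, %d chemicals\n",
              object@scope, nrow(res), nrow(object@hq)))
  if (nrow(res)) {
    cat(sprintf("HI range: %.3g-%.3g (median %.3g); %d flagged at HI >= %g\n",
                min(res$hi), max(res$hi), stats::median(res$hi),
                sum(res$risk_flag), object@config@risk_threshold))
  }
  if (length(object@unresolved))
    cat(sprintf("%d detected chemicals had no reference value or OEL\n",
                length(object@unresolved)))
  invisible(NULL)
})
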