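.normName <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

.casParts <- function(cas) {
  if (is.na(cas) || identical(cas, "NA") || !nzchar(trimws(cas)))
    return(character(0))
  trimws(strsplit(as.character(cas), ";", fixed = TRUE)[[1]])
}

# Row index of (name, cas) in the registry table: CAS is the primary join key
# (any overlap between the query's and the row's CAS group matches); the
# normalized chemical name is the fallback for grouped or CAS-less analytes.
.matchRegistry <- function(tab, name, cas = NA_character_) {
  q <- .casParts(cas)
  if (length(q)) {
    for (i in seq_len(nrow(tab))) {
      if (length(intersect(q, .casParts(tab$cas[i])))) return(i)
    }
  }
  hit <- which(.normName(tab$chemical) == .normName(name))
  if (length(hit)) hit[1L] else NA_integer_
}

.TIERS <- c("RV", "OEL_SE", "OEL_NORDIC", "OEL_INTL")
.TIER_COLS <- c(RV = "rv", OEL_SE = "oel_se", OEL_NORDIC = "oel_nordic",
                OEL_INTL = "oel_intl")

#' Resolve a chemical to its reference value through the tier hierarchy
#'
#' Returns the single limit value used as the hazard-quotient denominator,
#' following a strict ordered fallback: the chronic reference value if one
#' exists; otherwise the Swedish OEL; otherwise the lowest Nordic OEL;
#' otherwise the lowest international OEL. The hierarchy is strict by tier,
#' never by magnitude across tiers: a numerically lower OEL never overrides an
#' existing reference value. Within the Nordic and international tiers, where
#' several candidate limits may be on record, the lowest is chosen. A chemical
#' matched by no row, or matched by a row with all tiers blank, resolves to
#' \code{NULL}: it is excluded from hazard-index calculations (but still
#' counts toward TVOC).
#'
#' @param registry a [ReferenceRegistry-class].
#' @param name chemical name (fallback join key, case- and
#'   whitespace-insensitive).
#' @param cas CAS number, or a ";"-separated group of CAS (primary join key).
#' @param quiet suppress the once-per-call message for unresolved chemicals.
#' @return A list with \code{chemical}, \code{value} (ug/m3), \code{tier} (one
#'   of \code{"RV"}, \code{"OEL_SE"}, \code{"OEL_NORDIC"}, \code{"OEL_INTL"})
#'   and \code{source}; or \code{NULL} when unresolvable.
#' @examples
#' reg <- table3Registry()
#' resolveReference(reg, "Formaldehyde", "59-00-0")       # chronic RV, 9
#' resolveReference(reg, "2,4-Toluene diisocyanate")      # Swedish OEL, 14
#' resolveReference(reg, "Hedione")                       # NULL (excluded)
#' @export
resolveReference <- function(registry, name, cas = NA_character_,
                             quiet = FALSE) {
  stopifnot(is(registry, "ReferenceRegistry"))
  tab <- registry@table
  i <- .matchRegistry(tab, name, cas)
  if (!is.na(i)) {
    for (tier in .TIERS) {
      vals <- .parseLimits(tab[[.TIER_COLS[[tier]]]][i])
      if (length(vals)) {
        src <- tab[[paste0(.TIER_COLS[[tier]], "_source")]][i]
        return(list(chemical = tab$chemical[i], value = min(vals),
                    tier = tier,
                    source = if (is.na(src)) "" else src))
      }
    }
  }
  if (!quiet)
    message("no reference value or OEL found for '", name,
            "'; excluded from hazard-index calculations")
  NULL
}

# Vectorized resolution for the rows of an ExposureExperiment; one message
# per unresolved chemical per call.
.resolveAll <- function(registry, chemicals, quiet = TRUE) {
  n <- nrow(chemicals)
  value <- rep(NA_real_, n)
  tier <- rep(NA_character_, n)
  source <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    r <- resolveReference(registry, chemicals$name[k],
                          as.character(chemicals$cas[k]), quiet = quiet)
    if (!is.null(r)) {
      value[k] <- r$value
      tier[k] <- r$tier
      source[k] <- r$source
    }
  }
  data.frame(name = chemicals$name, value = value, tier = tier,
             source = source, stringsAsFactors = FALSE)
}

#' Registry coverage of the chemicals detected in a campaign
#'
#' Reports how many of the detected chemicals (quantified or reported below
#' the reporting limit in at least one sample) resolve through each tier of
#' the reference-value hierarchy, and which remain unresolved. Unresolved
#' chemicals contribute to TVOC but are excluded from the hazard index, so a
#' large unresolved share flags likely underestimation of cumulative risk.
#'
#' @param samples an [ExposureExperiment-class].
#' @param registry a [ReferenceRegistry-class].
#' @return A list: \code{n_detected}, \code{counts} (named vector over RV,
#'   OEL_SE, OEL_NORDIC, OEL_INTL, unresolved), \code{fractions},
#'   and \code{unresolved} (data.frame of unresolved chemicals sorted by
#'   detection frequency, most frequent first).
#' @export
registryCoverage <- function(samples, registry) {
  stopifnot(is(samples, "ExposureExperiment"),
            is(registry, "ReferenceRegistry"))
  detected_in <- rowSums(!is.na(assay(samples, "concentration")) |
                           assay(samples, "censored"))
  rd <- as.data.frame(rowData(samples))
  keep <- detected_in > 0
  rd <- rd[keep, , drop = FALSE]
  detected_in <- detected_in[keep]
  counts <- stats::setNames(integer(length(.TIERS) + 1L),
                            c(.TIERS, "unresolved"))
  if (nrow(rd) == 0L)
    return(list(n_detected = 0L, counts = counts,
                fractions = counts * NA_real_,
                unresolved = data.frame(name = character(0),
                                        n_samples = integer(0))))
  res <- .resolveAll(registry, rd, quiet = TRUE)
  tier <- ifelse(is.na(res$tier), "unresolved", res$tier)
  for (t in names(counts)) counts[[t]] <- sum(tier == t)
  unres <- data.frame(name = rd$name[tier == "unresolved"],
                      n_samples = as.integer(detected_in[tier == "unresolved"]))
  unres <- unres[order(-unres$n_samples, unres$name), , drop = FALSE]
  rownames(unres) <- NULL
  list(n_detected = nrow(rd), counts = counts,
       fractions = counts / nrow(rd), unresolved = unres)
}
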