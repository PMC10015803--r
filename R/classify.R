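.MCR_GROUPS <- c("I", "II", "IIIA", "IIIB")

# Classify one (hi, max_hq, mcr) triple under the strict precedence
# I -> II -> IIIA -> IIIB. The raw group definitions overlap (maxHQ > 1 with
# MCR < 2 satisfies both I and IIIA); single-substance concern takes priority.
# Boundaries: maxHQ exactly 1 -> I; MCR exactly at the cutoff -> IIIB.
.classifyOne <- function(hi, max_hq, mcr, hq_col, config) {
  if (max_hq >= 1) {
    conc <- names(hq_col)[!is.na(hq_col) & hq_col >= 1]
    conc <- conc[order(-hq_col[conc])]
    list(group = "I", soc = conc,
         rationale = sprintf("maxHQ %.3g >= 1: single substance concern",
                             max_hq))
  } else if (hi < config@risk_threshold) {
    list(group = "II", soc = character(0),
         rationale = sprintf("HI %.3g < %g: low concern", hi,
                             config@risk_threshold))
  } else if (mcr < config@mcr_dominance_cutoff) {
    k <- .whichMaxLex(hq_col)
    list(group = "IIIA", soc = names(hq_col)[k],
         rationale = sprintf(
           "HI %.3g >= %g, MCR %.3g < %g: combined effect dominated by one substance",
           hi, config@risk_threshold, mcr, config@mcr_dominance_cutoff))
  } else {
    # name the top contributors jointly covering >= 90% of HI, best first
    ord <- order(-hq_col)
    ord <- ord[!is.na(hq_col[ord])]
    cum <- cumsum(hq_col[ord])
    n_needed <- which(cum >= 0.9 * hi)[1L]
    list(group = "IIIB", soc = names(hq_col)[ord[seq_len(n_needed)]],
         rationale = sprintf(
           "HI %.3g >= %g, MCR %.3g >= %g: combined effect by several substances",
           hi, config@risk_threshold, mcr, config@mcr_dominance_cutoff))
  }
}

#' Assign MCR substance groups
#'
#' Sorts each risk result into the standard maximum-cumulative-ratio screening
#' groups: \strong{I} (maxHQ at or above 1 - single substance concern),
#' \strong{II} (HI below 1 - low concern), \strong{IIIA} (HI at or above 1
#' with MCR below the dominance cutoff - combined effect dominated by one
#' substance) and \strong{IIIB} (combined effect of several substances). The
#' raw group conditions overlap, so they are evaluated in strict precedence
#' I, II, IIIA, IIIB, which makes the assignment exhaustive and mutually
#' exclusive for every result with at least one contributing chemical.
#'
#' Substances of concern are named per group: for I, every chemical with HQ at
#' or above 1 (largest first); for IIIA, the maxHQ chemical; for IIIB, the top
#' contributors jointly covering at least 90\% of HI in descending HQ order
#' (a reporting convention of this package).
#'
#' @param result a [RiskAssessment-class].
#' @param config a [RunConfig-class]; supplies the HI threshold and the MCR
#'   dominance cutoff.
#' @return data.frame with one row per result: \code{id}, \code{group}
#'   (\code{NA} for an unclassifiable result with no contributing chemicals),
#'   \code{substances_of_concern} (";"-joined) and \code{rationale}.
#' @examples
#' # built directly from a tiny two-chemical sample
#' ee <- ExposureExperiment(
#'   concentration = matrix(c(38, 58), 2, 1,
#'     dimnames = list(c("Formaldehyde", "Isopropanol"), "s1:h1")),
#'   chemicals = data.frame(name = c("Formaldehyde", "Isopropanol"),
#'     cas = c("59-00-0", "67-63-0"),
#'     chem_class = c("aldehyde", "VOC"), tvoc_included = TRUE),
#'   samples = data.frame(salon_id = "s1", worker_id = "h1",
#'     duration_min = 176))
#' classifyMCR(hazardIndex(ee, table3Registry()))
#' @export
classifyMCR <- function(result, config = runConfig()) {
  stopifnot(is(result, "RiskAssessment"), is(config, "RunConfig"))
  res <- riskResults(result)
  hq <- hqMatrix(result)
  n <- nrow(res)
  group <- rep(NA_character_, n)
  soc <- rep("", n)
  rationale <- rep("no contributing chemicals: unclassifiable", n)
  for (j in seq_len(n)) {
    if (res$n_contributing[j] < 1L) next
    a <- .classifyOne(res$hi[j], res$max_hq[j], res$mcr[j],
                      stats::setNames(hq[, j], rownames(hq)), config)
    group[j] <- a$group
    soc[j] <- paste(a$soc, collapse = ";")
    rationale[j] <- a$rationale
  }
  data.frame(id = res$id, group = group, substances_of_concern = soc,
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Tally MCR substance groups over a cohort
#'
#' @param results a [RiskAssessment-class] or a list of them (e.g. the
#'   sample-scope and salon-scope assessments of one campaign).
#' @param config a [RunConfig-class].
#' @return A list with \code{tally} (data.frame of counts per scope and
#'   group) and \code{assignments} (per-result scope, id, group and
#'   substances of concern).
#' @export
classifyCohort <- function(results, config = runConfig()) {
  if (is(results, "RiskAssessment")) results <- list(results)
  stopifnot(all(vapply(results, is, logical(1), "RiskAssessment")))
  assignments <- do.call(rbind, lapply(results, function(r) {
    cbind(scope = r@scope, classifyMCR(r, config))
  }))
  if (is.null(assignments))
    assignments <- data.frame(scope = character(0), id = character(0),
                              group = character(0),
                              substances_of_concern = character(0),
                              rationale = character(0))
  tallies <- expand.grid(scope = unique(assignments$scope),
                         group = .MCR_GROUPS, stringsAsFactors = FALSE)
  if (nrow(tallies)) {
    tallies$n <- mapply(function(s, g) {
      sum(assignments$scope == s & !is.na(assignments$group) &
            assignments$group == g)
    }, tallies$scope, tallies$group)
    rownames(tallies) <- NULL
  } else {
    tallies <- data.frame(scope = character(0), group = character(0),
                          n = integer(0))
  }
  list(tally = tallies, assignments = assignments)
}
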