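#' Total VOC concentration per sample
#'
#' Sums the quantified concentrations of all analytes flagged as members of
#' the TVOC elution window (hexane to hexadecane; by convention aldehydes are
#' included by default and can be excluded through the per-chemical
#' \code{tvoc_included} flag). Censored (below reporting limit) and
#' non-detected analytes contribute nothing.
#'
#' @param sample an [ExposureExperiment-class].
#' @return Named numeric vector of TVOC (ug/m3 toluene equivalents), one per
#'   sample; 0 for a fully censored sample.
#' @export
computeTVOC <- function(sample) {
  stopifnot(is(sample, "ExposureExperiment"))
  conc <- assay(sample, "concentration")
  keep <- as.logical(rowData(sample)$tvoc_included)
  out <- colSums(conc[keep, , drop = FALSE], na.rm = TRUE)
  stats::setNames(as.numeric(out), colnames(sample))
}

#' Hazard quotient of a single chemical
#'
#' The ratio of a measured air concentration to the chemical's health-based
#' reference value (or fallback OEL): \code{HQ = C / RV}. Values at or above
#' 1 indicate that a single substance alone exceeds its chronic guideline.
#'
#' @param c concentration in ug/m3, positive (vectorized).
#' @param ref a resolved reference entry as returned by [resolveReference()],
#'   or directly a positive limit value in ug/m3.
#' @return \code{c / ref} at full precision.
#' @examples
#' hazardQuotient(38, 9)    # 4.22..., printed as 4 at one significant figure
#' hazardQuotient(58, 7)    # 8.29...
#' @export
hazardQuotient <- function(c, ref) {
  value <- if (is.list(ref)) ref$value else ref
  if (!is.numeric(c) || any(!is.finite(c)) || any(c <= 0))
    stop("concentration must be positive", call. = FALSE)
  if (!is.numeric(value) || length(value) < 1L || any(!is.finite(value)) ||
      any(value <= 0))
    stop("reference value must be positive", call. = FALSE)
  c / value
}

# id of the maximum entry with lexicographic tie-break on names
.whichMaxLex <- function(x) {
  m <- max(x, na.rm = TRUE)
  cand <- which(!is.na(x) & x == m)
  if (length(cand) > 1L) {
    cand <- cand[order(names(x)[cand])]
    message("maxHQ tie between ", paste(names(x)[cand], collapse = ", "),
            "; broken lexicographically")
  }
  cand[1L]
}

# Assemble a RiskAssessment from an HQ matrix (chemicals x results)
.buildRisk <- function(hq, tvoc, ids, salon_ids, scope, unresolved, config) {
  n <- ncol(hq)
  hi <- colSums(hq, na.rm = TRUE)
  n_contributing <- colSums(!is.na(hq))
  max_hq <- numeric(n)
  max_chem <- rep(NA_character_, n)
  mcr <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    if (n_contributing[j] >= 1L) {
      col <- stats::setNames(hq[, j], rownames(hq))
      k <- .whichMaxLex(col)
      max_hq[j] <- col[[k]]
      max_chem[j] <- rownames(hq)[k]
      if (max_hq[j] > 0) mcr[j] <- hi[j] / max_hq[j]
    }
  }
  res <- DataFrame(
    id = ids, salon_id = salon_ids, tvoc = as.numeric(tvoc),
    hi = as.numeric(hi), max_hq = max_hq, max_hq_chemical = max_chem,
    mcr = mcr, n_contributing = as.integer(n_contributing),
    risk_flag = hi >= config@risk_threshold)
  new("RiskAssessment", scope = scope, results = res, hq = hq,
      tvoc_by_result = as.numeric(tvoc), unresolved = unresolved,
      config = config)
}

#' Per-sample hazard index
#'
#' Computes a hazard quotient for every quantified analyte with a resolvable
#' reference value, sums them into the hazard index \code{HI = sum(HQ_i)}, and
#' derives the maximum HQ and the maximum cumulative ratio per sample.
#' Censored analytes and analytes with no reference value or OEL contribute
#' nothing to HI (the latter are listed in the result and contribute to TVOC
#' only).
#'
#' @param sample an [ExposureExperiment-class] (censoring already enforced at
#'   ingest).
#' @param registry a [ReferenceRegistry-class].
#' @param config a [RunConfig-class]; sets the HI risk threshold.
#' @return A sample-scope [RiskAssessment-class].
#' @examples
#' ee <- ExposureExperiment(
#'   concentration = matrix(c(38, 58), 2, 1,
#'     dimnames = list(c("Formaldehyde", "Isopropanol"), "s1:h1")),
#'   chemicals = data.frame(name = c("Formaldehyde", "Isopropanol"),
#'     cas = c("59-00-0", "67-63-0"),
#'     chem_class = c("aldehyde", "VOC"), tvoc_included = TRUE),
#'   samples = data.frame(salon_id = "s1", worker_id = "h1",
#'     duration_min = 176))
#' risk <- hazardIndex(ee, table3Registry())
#' riskResults(risk)$hi  # 38/9 + 58/7 = 12.507...
#' @export
hazardIndex <- function(sample, registry, config = runConfig()) {
  stopifnot(is(sample, "ExposureExperiment"),
            is(registry, "ReferenceRegistry"), is(config, "RunConfig"))
  conc <- assay(sample, "concentration")
  rd <- as.data.frame(rowData(sample))
  res <- if (nrow(rd)) .resolveAll(registry, rd, quiet = TRUE) else
    data.frame(value = numeric(0))
  hq <- conc / res$value  # rows with NA value -> all-NA row
  dimnames(hq) <- dimnames(conc)

  detected_in <- rowSums(!is.na(conc) | assay(sample, "censored"))
  unresolved <- rd$name[is.na(res$value) & detected_in > 0]
  if (length(unresolved))
    message(length(unresolved),
            " detected chemical(s) had no reference value or OEL and are excluded from HI: ",
            paste(unresolved, collapse = ", "))

  out <- .buildRisk(hq, computeTVOC(sample), colnames(sample),
                    as.character(colData(sample)$salon_id), "sample",
                    as.character(unresolved), config)
  if (any(riskResults(out)$n_contributing == 0L) && ncol(sample))
    warning("sample(s) with no contributing chemicals: HI reported as 0 (",
            paste(riskResults(out)$id[riskResults(out)$n_contributing == 0L],
                  collapse = ", "), ")", call. = FALSE)
  out
}

#' Maximum hazard quotient per result
#'
#' @param result a [RiskAssessment-class].
#' @return data.frame with one row per result: \code{id}, \code{chemical}
#'   attaining the maximum HQ (ties broken by lexicographic chemical name)
#'   and its \code{hq}; rows with no contributing chemical carry \code{NA}.
#' @export
maxHQ <- function(result) {
  stopifnot(is(result, "RiskAssessment"))
  res <- riskResults(result)
  data.frame(id = res$id, chemical = res$max_hq_chemical, hq = res$max_hq)
}

#' Maximum cumulative ratio
#'
#' \code{MCR = HI / maxHQ}: how many-fold the cumulative hazard exceeds its
#' single largest contributor. MCR near 1 means one substance drives the
#' mixture risk; MCR near the number of contributing chemicals means risk is
#' spread evenly across them.
#'
#' @param hi hazard index (vectorized).
#' @param max_hq the largest contributing hazard quotient.
#' @return \code{hi / max_hq}; \code{NA} (undefined, never a division by
#'   zero) where \code{max_hq} is 0.
#' @export
maximumCumulativeRatio <- function(hi, max_hq) {
  if (any(max_hq < 0) || any(hi < max_hq))
    stop("require hi >= max_hq >= 0", call. = FALSE)
  out <- ifelse(max_hq > 0, hi / max_hq, NA_real_)
  if (any(max_hq == 0))
    message("MCR undefined where maxHQ is 0")
  out
}

#' Aggregate per-sample risk results to the salon level
#'
#' The salon-level hazard-quotient map is the arithmetic mean of the per-sample
#' maps of that salon's workers, treating a chemical absent from a sample's
#' map as contributing 0 there. HI, maxHQ and MCR are recomputed from the mean
#' map; since means commute with the HI summation, the salon HI equals the
#' arithmetic mean of the worker HIs. Salon TVOC is likewise the mean of
#' sample TVOCs.
#'
#' @param results a sample-scope [RiskAssessment-class].
#' @param salons optional character vector restricting which salons to
#'   aggregate (requesting an unknown salon is an error).
#' @return A salon-scope [RiskAssessment-class], one result per salon.
#' @export
salonAggregate <- function(results, salons = NULL) {
  stopifnot(is(results, "RiskAssessment"))
  if (results@scope != "sample")
    stop("salonAggregate expects sample-scope results", call. = FALSE)
  res <- riskResults(results)
  ids <- unique(res$salon_id)
  if (!is.null(salons)) {
    if (!all(salons %in% ids))
      stop("unknown salon id(s): ",
           paste(setdiff(salons, ids), collapse = ", "), call. = FALSE)
    ids <- salons
  }
  if (length(ids) == 0L || anyNA(ids))
    stop("sample results carry no valid salon ids", call. = FALSE)
  hq <- hqMatrix(results)
  agg <- matrix(NA_real_, nrow(hq), length(ids),
                dimnames = list(rownames(hq), ids))
  tvoc <- numeric(length(ids))
  for (k in seq_along(ids)) {
    cols <- which(res$salon_id == ids[k])
    if (!all(res$salon_id[cols] == ids[k]))
      stop("mixed salon ids in aggregation group", call. = FALSE)
    sub <- hq[, cols, drop = FALSE]
    contributing <- rowSums(!is.na(sub)) > 0
    m <- rowMeans(replace(sub, is.na(sub), 0))
    agg[contributing & m > 0, k] <- m[contributing & m > 0]
    tvoc[k] <- mean(results@tvoc_by_result[cols])
  }
  .buildRisk(agg, tvoc, ids, ids, "salon", results@unresolved,
             results@config)
}
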