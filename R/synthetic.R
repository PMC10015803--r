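#' Configuration of a synthetic measurement campaign
#'
#' Describes the statistical structure the risk pipeline assumes: a panel of
#' chemicals with lognormal (GM, GSD) concentrations and per-chemical
#' detection probabilities, measured on \code{workers_per_salon} workers in
#' each of \code{n_salons} salons, with a per-(salon, chemical) random effect
#' carrying \code{between_frac} of the log-scale variance, and censoring at
#' the class-specific reporting limits. The defaults emulate a 10-salon,
#' 3-workers-per-salon campaign with the packaged panel and a between-salon
#' share of 28\% of variance, the structure reported for Swedish hair salons.
#'
#' @slot n_salons,workers_per_salon positive integers (defaults 10 and 3).
#' @slot chemicals data.frame with columns \code{name}, \code{cas},
#'   \code{chem_class}, \code{tvoc_included}, \code{gm} (ug/m3), \code{gsd}
#'   (>= 1) and \code{detect_prob} (in [0, 1]).
#' @slot between_frac share of log-scale variance attributed to the salon
#'   effect, in [0, 1) (default 0.28).
#' @slot reporting_limits a [ReportingLimits-class].
#' @slot seed integer seed making generation fully deterministic.
#' @export
setClass("SyntheticConfig",
  representation(n_salons = "integer", workers_per_salon = "integer",
                 chemicals = "data.frame", between_frac = "numeric",
                 reporting_limits = "ReportingLimits", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  ch <- object@chemicals
  need <- c("name", "cas", "chem_class", "tvoc_included", "gm", "gsd",
            "detect_prob")
  if (!all(need %in% colnames(ch)))
    return(paste("chemicals must contain:", paste(need, collapse = ", ")))
  if (object@n_salons < 1L || object@workers_per_salon < 1L)
    return("n_salons and workers_per_salon must be positive")
  if (any(ch$gm <= 0)) return("every gm must be positive")
  if (any(ch$gsd < 1)) return("every gsd must be >= 1")
  if (any(ch$detect_prob < 0 | ch$detect_prob > 1))
    return("detect_prob must lie in [0, 1]")
  if (object@between_frac < 0 || object@between_frac >= 1)
    return("between_frac must lie in [0, 1)")
  TRUE
})

#' The packaged default chemical panel
#'
#' Loads the panel of VOCs and aldehydes (name, CAS, class, TVOC-window
#' membership, geometric mean, geometric standard deviation and detection
#' probability) used as the default for synthetic campaigns. The panel mirrors
#' the selection of analytes with significant exposure contributions in a
#' Swedish hair-salon campaign; detection probabilities are detection counts
#' out of 30 samples, and singleton or constant analytes carry GSD 1. Two
#' analytes whose published concentrations sat entirely below the VOC
#' reporting limit carry a synthetic stand-in GM below 3 ug/m3.
#'
#' @return data.frame suitable for the \code{chemicals} slot of
#'   [syntheticConfig()].
#' @export
table3Panel <- function() {
  p <- utils::read.csv(system.file("extdata", "table3_panel.csv",
                                   package = "vocmix", mustWork = TRUE),
                       colClasses = c(name = "character", cas = "character",
                                      chem_class = "character"),
                       check.names = FALSE)
  p$tvoc_included <- as.logical(p$tvoc_included)
  p
}

#' @rdname SyntheticConfig-class
#' @param n_salons,workers_per_salon campaign dimensions.
#' @param chemicals chemical panel (see slot description); defaults to
#'   [table3Panel()].
#' @param between_frac between-salon share of log-scale variance.
#' @param reporting_limits a [ReportingLimits-class].
#' @param seed integer seed.
#' @export
syntheticConfig <- function(n_salons = 10L, workers_per_salon = 3L,
                            chemicals = table3Panel(), between_frac = 0.28,
                            reporting_limits = reportingLimits(),
                            seed = 1L) {
  new("SyntheticConfig", n_salons = as.integer(n_salons),
      workers_per_salon = as.integer(workers_per_salon),
      chemicals = as.data.frame(chemicals),
      between_frac = as.numeric(between_frac),
      reporting_limits = reporting_limits, seed = as.integer(seed))
}

#' Generate a synthetic measurement campaign
#'
#' For each (salon, worker, chemical) the analyte is detected with probability
#' \code{detect_prob} (a Bernoulli gate modelling true absence); if detected,
#' the concentration is \code{gm * exp(b_salon + e)} with
#' \code{b_salon ~ N(0, between_frac * sigma^2)} drawn once per
#' (salon, chemical) and \code{e ~ N(0, (1 - between_frac) * sigma^2)} per
#' worker, where \code{sigma = log(gsd)}. Generated values below the
#' class-specific reporting limit are then censored exactly as real data
#' would be (present but carrying no numeric value). Both mechanisms -
#' absence and below-limit censoring - occur in real campaigns. Generation is
#' fully deterministic given \code{config@seed}.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with \code{experiment} (the censored
#'   [ExposureExperiment-class] as a real campaign would be read) and
#'   \code{truth}: the uncensored concentration matrix, the detection gate
#'   matrix, the per-(chemical, salon) random effects, and the config.
#' @examples
#' camp <- generateCampaign(syntheticConfig(seed = 7L))
#' camp$experiment
#' @export
generateCampaign <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(config@seed)
  ch <- config@chemicals
  ns <- config@n_salons
  nw <- config@workers_per_salon
  n <- ns * nw
  salon <- rep(sprintf("salon%02d", seq_len(ns)), each = nw)
  worker <- paste0("w", rep(seq_len(nw), times = ns))
  sigma <- log(ch$gsd)
  sb <- sqrt(config@between_frac) * sigma
  sw <- sqrt(1 - config@between_frac) * sigma

  nc <- nrow(ch)
  b <- matrix(stats::rnorm(nc * ns, 0, rep(sb, ns)), nc, ns)
  e <- matrix(stats::rnorm(nc * n, 0, rep(sw, n)), nc, n)
  conc_true <- ch$gm * exp(b[, rep(seq_len(ns), each = nw), drop = FALSE] + e)
  detected <- matrix(stats::runif(nc * n) < ch$detect_prob, nc, n)

  rl <- ifelse(ch$chem_class == "aldehyde",
               config@reporting_limits@aldehyde_limit,
               config@reporting_limits@voc_limit)
  censored <- detected & (conc_true < rl)
  conc <- ifelse(detected & !censored, conc_true, NA_real_)
  dimnames(conc_true) <- dimnames(conc) <- dimnames(censored) <-
    list(ch$name, paste(salon, worker, sep = ":"))

  ee <- ExposureExperiment(
    concentration = conc, censored = censored,
    chemicals = ch[, c("name", "cas", "chem_class", "tvoc_included")],
    samples = data.frame(salon_id = salon, worker_id = worker,
                         duration_min = 176),
    reporting_limits = config@reporting_limits)
  list(experiment = ee,
       truth = list(concentration = conc_true, detected = detected,
                    salon_effects = b, config = config))
}

#' Generate per-salon indoor-climate records
#'
#' Draws salon-mean CO2 around 628 ppm (lognormal, default CV 32\%), air
#' temperature around 23.2 deg C and relative humidity around 37.9\%, the
#' normal-condition averages of the emulated campaign. A nonzero
#' \code{co2_exposure_slope} couples CO2 to each salon's mean TVOC (centered),
#' planting a positive ventilation-driven association so that CO2-exposure
#' regressions have a recoverable signal. With \code{co2_cv = 0} and zero
#' slope every salon sits exactly at \code{co2_mean}.
#'
#' @param campaign a campaign from [generateCampaign()].
#' @param co2_exposure_slope ppm increase per ug/m3 of salon-mean TVOC.
#' @param co2_mean,co2_cv CO2 arithmetic mean (ppm) and coefficient of
#'   variation.
#' @param temp_mean,temp_cv temperature mean (deg C) and CV.
#' @param rh_mean,rh_cv relative humidity mean (percent) and CV.
#' @param seed optional integer; when supplied, climate generation is
#'   deterministic on its own.
#' @return data.frame of climate records: \code{salon_id}, \code{co2_ppm},
#'   \code{temp_c}, \code{rh_pct}.
#' @export
generateClimate <- function(campaign, co2_exposure_slope = 0,
                            co2_mean = 628, co2_cv = 0.32,
                            temp_mean = 23.2, temp_cv = 0.044,
                            rh_mean = 37.9, rh_cv = 0.31, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ee <- campaign$experiment
  salons <- unique(as.character(colData(ee)$salon_id))
  tvoc <- computeTVOC(ee)
  tvoc_salon <- tapply(tvoc, as.character(colData(ee)$salon_id),
                       mean)[salons]
  ns <- length(salons)
  draw_ln <- function(m, cv) {
    if (cv == 0) return(rep(m, ns))
    s2 <- log(1 + cv^2)  # lognormal with arithmetic mean m and CV cv
    m * exp(stats::rnorm(ns, -s2 / 2, sqrt(s2)))
  }
  co2 <- draw_ln(co2_mean, co2_cv) +
    co2_exposure_slope * (tvoc_salon - mean(tvoc_salon))
  data.frame(salon_id = salons,
             co2_ppm = pmax(co2, 301),
             temp_c = draw_ln(temp_mean, temp_cv),
             rh_pct = pmin(pmax(draw_ln(rh_mean, rh_cv), 0), 100),
             row.names = NULL)
}
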