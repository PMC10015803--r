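#' Descriptive statistics for one chemical's detected concentrations
#'
#' Computes the standard occupational-hygiene descriptives over the detected
#' (uncensored) values of one analyte: arithmetic mean, sample SD (n-1
#' denominator), geometric mean \code{exp(mean(log x))}, geometric standard
#' deviation \code{exp(sd(log x))}, median, minimum and maximum. The GSD of a
#' singleton or constant series is defined as 1, the multiplicative identity
#' (not 0, which some published tables print in that case). No imputation of
#' censored values (such as RL/sqrt(2)) is applied.
#'
#' @param values positive concentrations from detected samples, length >= 1.
#' @return One-row data.frame: \code{n_detected}, \code{am}, \code{sd},
#'   \code{gm}, \code{gsd}, \code{median}, \code{min}, \code{max}. \code{sd}
#'   is \code{NA} for a singleton.
#' @examples
#' describeChemical(c(2, 8))   # gm 4
#' describeChemical(c(6, 6))   # am 6, sd 0, gsd 1
#' @export
describeChemical <- function(values) {
  if (length(values) < 1L)
    stop("need at least one detected value", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("concentrations must be positive (geometric mean undefined otherwise)",
         call. = FALSE)
  n <- length(values)
  lx <- log(values)
  gsd <- if (n == 1L) 1 else exp(stats::sd(lx))
  data.frame(n_detected = n, am = mean(values),
             sd = if (n == 1L) NA_real_ else stats::sd(values),
             gm = exp(mean(lx)), gsd = gsd,
             median = stats::median(values), min = min(values),
             max = max(values))
}

#' Campaign-wide per-chemical summary table
#'
#' Applies [describeChemical()] to every chemical detected in at least one
#' sample and, when a registry is supplied, appends the maximum hazard
#' quotient (from the detected maximum and the resolved limit value), the
#' resolved limit and its tier.
#'
#' @param samples an [ExposureExperiment-class].
#' @param registry optional [ReferenceRegistry-class].
#' @return data.frame, one row per detected chemical. \code{n_detected}
#'   counts samples where the chemical was reported (quantified or censored);
#'   the statistics cover quantified values only.
#' @export
summarizeChemicals <- function(samples, registry = NULL) {
  stopifnot(is(samples, "ExposureExperiment"))
  conc <- assay(samples, "concentration")
  cen <- assay(samples, "censored")
  rd <- as.data.frame(rowData(samples))
  rows <- which(rowSums(!is.na(conc) | cen) > 0)
  out <- do.call(rbind, lapply(rows, function(i) {
    v <- conc[i, !is.na(conc[i, ])]
    stats <- if (length(v)) describeChemical(v) else
      data.frame(n_detected = 0L, am = NA_real_, sd = NA_real_, gm = NA_real_,
                 gsd = NA_real_, median = NA_real_, min = NA_real_,
                 max = NA_real_)
    stats$n_detected <- sum(!is.na(conc[i, ]) | cen[i, ])
    cbind(data.frame(chemical = rd$name[i], cas = as.character(rd$cas[i])),
          stats)
  }))
  if (is.null(out))
    return(data.frame(chemical = character(0)))
  rownames(out) <- NULL
  if (!is.null(registry)) {
    res <- .resolveAll(registry, data.frame(name = out$chemical,
                                            cas = out$cas), quiet = TRUE)
    out$max_hq <- ifelse(is.na(res$value) | is.na(out$max), NA_real_,
                         out$max / res$value)
    out$limit_value <- res$value
    out$limit_tier <- res$tier
  }
  out
}

#' One-way random-effects variance components (method of moments)
#'
#' Partitions the variance of a response grouped by salon into between-salon
#' and within-salon (between-worker) components using the classical one-way
#' ANOVA method of moments: \code{within = MS_within} and \code{between =
#' max(0, (MS_between - MS_within) / n0)}, with \code{n0} the standard
#' unbalanced-design coefficient (the common group size when balanced). A
#' negative moment estimate is truncated to 0. When \code{x} is a matrix
#' (chemicals x samples, e.g. log concentrations of a whole panel), components
#' are estimated per row and a pooled between-group fraction is reported as
#' the mean of the per-row fractions - at typical campaign sizes (10 salons of
#' 3 workers) a single response yields a very noisy fraction, and pooling
#' across a panel is how the package recovers the design fraction.
#'
#' @param x numeric vector of responses (e.g. per-worker HI or TVOC), or a
#'   matrix with one response per row.
#' @param groups grouping factor (salon ids), one per sample/column.
#' @return For a vector: list with \code{between_var}, \code{within_var},
#'   \code{between_frac}, \code{within_frac}, \code{ms_between},
#'   \code{ms_within}, \code{n0}. Fractions are \code{NA} when the total
#'   variance is 0. For a matrix: list with \code{per_row} (data.frame) and
#'   \code{pooled_between_frac}.
#' @examples
#' varianceComponents(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(1:3, each = 3))
#' @export
varianceComponents <- function(x, groups) {
  if (is.matrix(x)) {
    per <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
      vc <- varianceComponents(x[i, ], groups)
      data.frame(between_var = vc$between_var, within_var = vc$within_var,
                 between_frac = vc$between_frac,
                 within_frac = vc$within_frac)
    }))
    rownames(per) <- rownames(x)
    return(list(per_row = per,
                pooled_between_frac = mean(per$between_frac, na.rm = TRUE)))
  }
  groups <- as.factor(groups)
  stopifnot(length(x) == length(groups))
  g <- nlevels(droplevels(groups))
  N <- length(x)
  if (g < 2L) stop("need at least two groups", call. = FALSE)
  if (N == g)
    stop("all groups of size 1: within-group component undefined",
         call. = FALSE)
  ni <- as.numeric(table(droplevels(groups)))
  means <- tapply(x, droplevels(groups), mean)
  grand <- mean(x)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((x - means[droplevels(groups)])^2)
  ms_between <- ssb / (g - 1)
  ms_within <- ssw / (N - g)
  n0 <- (N - sum(ni^2) / N) / (g - 1)
  between <- max(0, (ms_between - ms_within) / n0)
  total <- between + ms_within
  list(between_var = between, within_var = ms_within,
       between_frac = if (total > 0) between / total else NA_real_,
       within_frac = if (total > 0) ms_within / total else NA_real_,
       ms_between = ms_between, ms_within = ms_within, n0 = n0)
}

#' One-way ANOVA with optional Bonferroni pairwise comparisons
#'
#' Classical fixed-effects one-way ANOVA: \code{F = MS_between / MS_within}
#' on \code{(g - 1, N - g)} degrees of freedom. When within-group variance is
#' exactly 0 with unequal group means the design is degenerate and F is
#' reported as \code{Inf} with p = 0 and a flag; when all group means are
#' equal F is 0 with p = 1. Pairwise comparisons are two-sided t-tests on
#' group means with the pooled SD and Bonferroni-adjusted p-values (raw p
#' multiplied by the number of pairs, capped at 1), via
#' [stats::pairwise.t.test()].
#'
#' @param x numeric responses.
#' @param groups grouping factor.
#' @param pairwise also compute the Bonferroni pairwise table.
#' @return list: \code{f}, \code{df1}, \code{df2}, \code{p},
#'   \code{degenerate}, and (if requested) \code{pairwise}, the matrix of
#'   adjusted p-values.
#' @export
anovaOneway <- function(x, groups, pairwise = FALSE) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(x) == length(groups))
  g <- nlevels(groups)
  N <- length(x)
  if (g < 2L) stop("need at least two groups", call. = FALSE)
  if (N <= g) stop("need total n greater than the number of groups",
                   call. = FALSE)
  ni <- as.numeric(table(groups))
  means <- tapply(x, groups, mean)
  ssb <- sum(ni * (means - mean(x))^2)
  ssw <- sum((x - means[groups])^2)
  df1 <- g - 1L
  df2 <- N - g
  ms_between <- ssb / df1
  ms_within <- ssw / df2
  degenerate <- FALSE
  if (ms_within == 0 && ms_between > 0) {
    f <- Inf
    p <- 0
    degenerate <- TRUE
    warning("zero within-group variance with unequal means: degenerate design",
            call. = FALSE)
  } else if (ms_between == 0) {
    f <- 0
    p <- 1
  } else {
    f <- ms_between / ms_within
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  out <- list(f = f, df1 = df1, df2 = df2, p = p, degenerate = degenerate)
  if (pairwise) {
    out$pairwise <- stats::pairwise.t.test(
      x, groups, p.adjust.method = "bonferroni", pool.sd = TRUE)$p.value
  }
  out
}

#' Ordinary least squares fit of y on x
#'
#' Simple linear regression via [stats::lm()], returning the slope, intercept,
#' coefficient of determination and the two-sided p-value for the slope from
#' the t distribution on n - 2 degrees of freedom. A constant response yields
#' slope 0 and R-squared 0 (p reported as 1: no evidence of dependence).
#'
#' @param x predictor, not constant, length >= 3.
#' @param y response, same length.
#' @return list: \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_value}, \code{n}.
#' @examples
#' olsFit(c(1, 2, 3), c(1, 2, 2))  # slope 0.5, intercept 2/3
#' @export
olsFit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("singular design: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # a perfect fit is a legitimate input; silence summary.lm's note about it
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  if (stats::sd(y) == 0) {
    return(list(slope = 0, intercept = mean(y), r_squared = 0, p_value = 1,
                n = length(x)))
  }
  list(slope = co["x", "Estimate"], intercept = co["(Intercept)", "Estimate"],
       r_squared = sm$r.squared, p_value = co["x", "Pr(>|t|)"],
       n = length(x))
}
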