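test_that("TVOC sums quantified window members and nothing else", {
  # fully censored sample
  ee <- ee_from_matrix(matrix(NA_real_, 2, 1, dimnames = list(c("a", "b"), NULL)),
                       censored = matrix(TRUE, 2, 1))
  expect_equal(unname(computeTVOC(ee)), 0)

  ee2 <- ee_from_matrix(matrix(c(37, 200, 15), 3, 1,
                               dimnames = list(c("a", "b", "c"), NULL)))
  expect_equal(unname(computeTVOC(ee2)), 252)

  ee3 <- ee_from_matrix(matrix(c(37, 50), 2, 1,
                               dimnames = list(c("a", "b"), NULL)),
                        tvoc_included = c(TRUE, FALSE))
  expect_equal(unname(computeTVOC(ee3)), 37)
})

test_that("hazard quotients are exact ratios with domain checks", {
  expect_equal(hazardQuotient(38, 9), 38 / 9)
  expect_equal(signif(hazardQuotient(38, 9), 1), 4)
  expect_equal(signif(hazardQuotient(58, 7), 1), 8)
  expect_equal(hazardQuotient(5, list(value = 5, tier = "RV")), 1)
  expect_error(hazardQuotient(-1, 9), "positive")
  expect_error(hazardQuotient(1, 0), "positive")
})

test_that("hazard index sums quotients over resolvable, uncensored analytes", {
  reg <- registry_rv(c("Formaldehyde", "Isopropanol"), c(9, 7))
  ee <- ee_from_matrix(matrix(c(38, 58), 2, 1,
    dimnames = list(c("Formaldehyde", "Isopropanol"), NULL)))
  risk <- hazardIndex(ee, reg)
  res <- riskResults(risk)
  expect_equal(res$hi, 38 / 9 + 58 / 7, tolerance = 1e-12)  # 12.5079...
  expect_equal(res$n_contributing, 2L)
  expect_equal(res$mcr, (38 / 9 + 58 / 7) / (58 / 7), tolerance = 1e-12)
  expect_identical(res$max_hq_chemical, "Isopropanol")
  expect_true(res$risk_flag)

  # single resolvable analyte: HI equals its HQ
  risk1 <- risk_from_hqs(list(c(only = 0.4)))
  expect_equal(riskResults(risk1)$hi, 0.4)
  expect_equal(riskResults(risk1)$mcr, 1)

  # only unresolved analytes: HI 0, n_contributing 0, warning
  ee_un <- ee_from_matrix(matrix(5, 1, 1, dimnames = list("mystery", NULL)))
  expect_warning(
    risk0 <- suppressMessages(hazardIndex(ee_un, registry_rv("other", 1))),
    "no contributing")
  expect_equal(riskResults(risk0)$hi, 0)
  expect_identical(riskResults(risk0)$n_contributing, 0L)
  expect_identical(unresolvedChemicals(risk0), "mystery")
})

test_that("maxHQ picks the largest quotient with lexicographic tie-break", {
  r <- risk_from_hqs(list(c(formaldehyde = 4.22, limonene = 0.69)))
  m <- maxHQ(r)
  expect_identical(m$chemical, "formaldehyde")
  expect_equal(m$hq, 4.22)

  tie <- suppressMessages(risk_from_hqs(list(c(b = 1.0, a = 1.0))))
  expect_identical(maxHQ(tie)$chemical, "a")
})

test_that("MCR is HI over maxHQ, undefined at zero, k for k equal contributors", {
  expect_equal(maximumCumulativeRatio(2, 1), 2)
  expect_true(is.na(suppressMessages(maximumCumulativeRatio(0, 0))))
  expect_error(maximumCumulativeRatio(1, 2), "hi >= max_hq")
  for (k in c(2, 5, 9)) {
    hqs <- stats::setNames(rep(0.37, k), sprintf("c%02d", seq_len(k)))
    r <- risk_from_hqs(list(hqs))
    expect_equal(riskResults(r)$mcr, k, tolerance = 1e-12)
  }
})

test_that("salon aggregation averages HQ maps with absent treated as zero", {
  # identical samples: aggregate equals any one of them
  same <- risk_from_hqs(list(c(a = 2, b = 1), c(a = 2, b = 1)),
                        salon = c("s1", "s1"))
  agg <- salonAggregate(same)
  expect_equal(riskResults(agg)$hi, 3)
  expect_equal(riskResults(agg)$max_hq, 2)

  # HIs {1, 3} over the same single chemical: aggregate HI 2
  r13 <- risk_from_hqs(list(c(a = 1), c(a = 3)), salon = c("s1", "s1"))
  expect_equal(riskResults(salonAggregate(r13))$hi, 2)

  # one contributing sample out of three: chemical-mean construction
  r300 <- suppressWarnings(risk_from_hqs(
    list(c(a = 3), c(b = NA)[0], c(b = NA)[0]), salon = rep("s1", 3)))
  expect_equal(riskResults(salonAggregate(r300))$hi, 1)

  # salon HI equals the mean of sample HIs; unknown salon errors
  multi <- risk_from_hqs(list(c(a = 1, b = 2), c(a = 2), c(b = 5)),
                         salon = c("s1", "s1", "s2"))
  agg2 <- salonAggregate(multi)
  res2 <- riskResults(agg2)
  expect_equal(res2$hi[res2$id == "s1"], mean(c(3, 2)))
  expect_equal(res2$hi[res2$id == "s2"], 5)
  expect_error(salonAggregate(multi, salons = "nope"), "unknown salon")
  expect_error(salonAggregate(agg2), "sample-scope")
})

test_that("HI respects ordering, additivity, censoring exclusion and scaling", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    chems <- sprintf("c%02d", seq_len(n))
    conc <- stats::setNames(round(stats::rlnorm(n, 3, 1), 4), chems)
    rvs <- stats::setNames(round(stats::rlnorm(n, 2, 1), 4), chems)
    ee <- ee_from_matrix(matrix(conc, n, 1, dimnames = list(chems, NULL)))
    reg <- registry_rv(chems, rvs)
    risk <- hazardIndex(ee, reg)
    res <- riskResults(risk)

    # brute-force oracle: independent per-chemical summation
    oracle <- sum(vapply(chems, function(ch) conc[[ch]] / rvs[[ch]],
                         numeric(1)))
    expect_equal(res$hi, oracle, tolerance = 1e-9)
    expect_gte(res$hi, res$max_hq)
    expect_gte(res$mcr, 1 - 1e-12)
    expect_lte(res$mcr, res$n_contributing + 1e-12)

    # permutation invariance
    perm <- sample(n)
    ee_p <- ee_from_matrix(matrix(conc[perm], n, 1,
                                  dimnames = list(chems[perm], NULL)))
    expect_equal(riskResults(hazardIndex(ee_p, reg))$hi, res$hi,
                 tolerance = 1e-12)

    # split-set additivity
    half <- seq_len(n %/% 2)
    if (length(half) >= 1 && length(half) < n) {
      hi_a <- riskResults(suppressWarnings(hazardIndex(
        ee_from_matrix(matrix(conc[half], length(half), 1,
                              dimnames = list(chems[half], NULL))), reg)))$hi
      hi_b <- riskResults(suppressWarnings(hazardIndex(
        ee_from_matrix(matrix(conc[-half], n - length(half), 1,
                              dimnames = list(chems[-half], NULL))), reg)))$hi
      expect_equal(hi_a + hi_b, res$hi, tolerance = 1e-9)
    }

    # adding censored and unresolved analytes changes nothing
    conc_x <- c(conc, extra_censored = NA_real_, extra_unresolved = 999)
    cen_x <- matrix(c(rep(FALSE, n), TRUE, FALSE), n + 2, 1)
    ee_x <- ee_from_matrix(matrix(conc_x, n + 2, 1,
                                  dimnames = list(names(conc_x), NULL)),
                           censored = cen_x)
    risk_x <- suppressMessages(hazardIndex(ee_x, reg))
    expect_equal(riskResults(risk_x)$hi, res$hi, tolerance = 1e-12)
    expect_equal(riskResults(risk_x)$mcr, res$mcr, tolerance = 1e-12)

    # scaling: lambda scales TVOC and HI, leaves MCR unchanged
    lam <- stats::runif(1, 0.1, 10)
    ee_s <- ee_from_matrix(matrix(lam * conc, n, 1,
                                  dimnames = list(chems, NULL)))
    risk_s <- hazardIndex(ee_s, reg)
    expect_equal(riskResults(risk_s)$hi, lam * res$hi, tolerance = 1e-9)
    expect_equal(unname(computeTVOC(ee_s)), lam * unname(computeTVOC(ee)),
                 tolerance = 1e-9)
    expect_equal(riskResults(risk_s)$mcr, res$mcr, tolerance = 1e-9)
  }
})
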