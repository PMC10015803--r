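test_that("measurement reader retains quantified values and censors below-limit rows", {
  rows <- rbind(
    measurement_row(chemical = "Formaldehyde", cas = "59-00-0",
                    chem_class = "aldehyde", conc = "38"),
    measurement_row(chemical = "Limonene", cas = "5989-27-5", conc = "2.5"),
    measurement_row(chemical = "Nonane", cas = "111-84-2", conc = "<RL"))
  expect_warning(ee <- readMeasurements(write_measurements_csv(rows)),
                 "below the reporting limit")
  conc <- SummarizedExperiment::assay(ee, "concentration")
  cen <- SummarizedExperiment::assay(ee, "censored")
  expect_equal(conc["Formaldehyde", 1], 38)
  expect_true(is.na(conc["Limonene", 1]))   # 2.5 < VOC limit 3
  expect_true(cen["Limonene", 1])
  expect_true(cen["Nonane", 1])             # explicit "<RL" token
  expect_identical(ncol(ee), 1L)
})

test_that("aldehyde and VOC reporting limits are applied per class", {
  rows <- rbind(
    measurement_row(chemical = "Acetaldehyde", chem_class = "aldehyde",
                    conc = "0.5"),  # above 0.3: retained
    measurement_row(chemical = "Acetone", conc = "0.5"))  # below 3: censored
  expect_warning(ee <- readMeasurements(write_measurements_csv(rows)))
  conc <- SummarizedExperiment::assay(ee, "concentration")
  expect_equal(conc["Acetaldehyde", 1], 0.5)
  expect_true(is.na(conc["Acetone", 1]))
})

test_that("an empty measurement file with a valid header yields zero samples", {
  path <- tempfile(fileext = ".csv")
  writeLines(paste("salon_id", "worker_id", "duration_min", "chemical",
                   "cas", "chem_class", "concentration", sep = ","), path)
  ee <- readMeasurements(path)
  expect_identical(ncol(ee), 0L)
  expect_identical(nrow(ee), 0L)
})

test_that("malformed measurement files fail with informative errors", {
  rows <- measurement_row()
  # missing required column, named in the error
  bad <- rows[, setdiff(colnames(rows), "chem_class")]
  expect_error(readMeasurements(write_measurements_csv(bad)), "chem_class")
  # non-numeric concentration other than "<RL", with the row number
  bad2 <- rbind(rows, measurement_row(chemical = "y", conc = "oops"))
  expect_error(readMeasurements(write_measurements_csv(bad2)), "row 2")
  # duplicate (salon, worker, chemical)
  bad3 <- rbind(rows, rows)
  expect_error(readMeasurements(write_measurements_csv(bad3)), "duplicate")
})

test_that("registry reader loads tiers, keeps multi-value cells, and validates", {
  reg <- table3Registry()
  f <- resolveReference(reg, "Formaldehyde", "59-00-0")
  expect_equal(f$value, 9)
  expect_null(suppressMessages(resolveReference(reg, "Hedione")))

  path <- tempfile(fileext = ".csv")
  writeLines(c("chemical,cas,rv,oel_intl",
               "synthchem,NA,,1000;2100"), path)
  r <- readRegistry(path)
  got <- resolveReference(r, "synthchem")
  expect_equal(got$value, 1000)  # both retained, lowest selected

  writeLines(c("chemical,cas,rv", "badchem,NA,-5"), path)
  expect_error(readRegistry(path), "must be > 0")
  writeLines(c("chemical,cas,rv,bogus", "x,NA,1,2"), path)
  expect_error(readRegistry(path), "unknown column")
})

test_that("report writer emits display rounding and round-trips full precision", {
  risk <- risk_from_hqs(list(c(Formaldehyde = 38 / 9)))
  path <- tempfile(fileext = ".csv")
  writeReport(risk, path)
  rep <- readReport(path)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$hi_display, "4")  # 4.222... at 1 significant figure
  expect_equal(rep$hi, 38 / 9, tolerance = 1e-12)

  # round trip is lossless to 12 significant digits for all numeric columns
  risk2 <- risk_from_hqs(list(c(a = 1.234567890123, b = 0.987654321098),
                              c(a = 2.345678901234)))
  writeReport(risk2, path)
  rep2 <- readReport(path)
  res2 <- riskResults(risk2)
  for (col in c("tvoc", "hi", "max_hq", "mcr"))
    expect_equal(rep2[[col]], res2[[col]], tolerance = 1e-12)
  # HQ breakdown file exists in long format
  hq_file <- paste0(tools::file_path_sans_ext(path), "_hq.csv")
  expect_true(file.exists(hq_file))
  br <- utils::read.csv(hq_file)
  expect_identical(nrow(br), 3L)
})

test_that("container validity rejects inconsistent censoring and duplicates", {
  expect_error(ExposureExperiment(
    concentration = matrix(5, 1, 1, dimnames = list("a", "s1:h1")),
    censored = matrix(TRUE, 1, 1),
    chemicals = data.frame(name = "a", cas = "NA", chem_class = "VOC",
                           tvoc_included = TRUE),
    samples = data.frame(salon_id = "s1", worker_id = "h1",
                         duration_min = 176)),
    "censored")
  expect_error(ee_from_matrix(matrix(c(1, 2), 1, 2), salon = c("s1", "s1"),
                              worker = c("h1", "h1")),
    "unique")
  expect_error(ee_from_matrix(matrix(-1, 1, 1)), "> 0")
})

test_that("run configuration files parse and validate", {
  path <- tempfile()
  writeLines(c("# thresholds", "voc_limit = 5", "risk_threshold = 1.5",
               "mcr_dominance_cutoff = 2.5"), path)
  cfg <- readRunConfig(path)
  expect_equal(cfg@reporting_limits@voc_limit, 5)
  expect_equal(cfg@reporting_limits@aldehyde_limit, 0.3)
  expect_equal(cfg@risk_threshold, 1.5)
  expect_equal(cfg@mcr_dominance_cutoff, 2.5)
  expect_error(runConfig(risk_threshold = 0), "positive")
  expect_error(reportingLimits(voc_limit = -3), "positive")
})

test_that("climate reader validates physical plausibility", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(salon_id = c("s1", "s2"),
                              co2_ppm = c(628, 1129),
                              temp_c = c(23.2, 24), rh_pct = c(37.9, 40)),
                   path, row.names = FALSE)
  cl <- readClimate(path)
  expect_identical(nrow(cl), 2L)
  utils::write.csv(data.frame(salon_id = "s1", co2_ppm = 120,
                              temp_c = 23, rh_pct = 40), path,
                   row.names = FALSE)
  expect_error(readClimate(path), "300")
})

test_that("the command-line wrapper simulates, computes and signals validation errors", {
  script <- system.file("scripts", "vocmix.R", package = "vocmix")
  rscript <- file.path(R.home("bin"), "Rscript")
  sim <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  s1 <- system2(rscript, c(script, "simulate", "--seed", "3", "--out", sim),
                stdout = TRUE, stderr = TRUE)
  expect_identical(attr(s1, "status"), NULL)  # exit 0
  expect_true(file.exists(sim))
  expect_true(file.exists(sub("\\.csv$", "_truth.csv", sim)))
  s2 <- system2(rscript, c(script, "compute", "--measurements", sim,
                           "--registry",
                           system.file("extdata", "table3_registry.csv",
                                       package = "vocmix"),
                           "--out", out), stdout = TRUE, stderr = TRUE)
  expect_identical(attr(s2, "status"), NULL)
  expect_gt(nrow(readReport(out)), 0)
  # validation failure exits with status 2
  s3 <- suppressWarnings(
    system2(rscript, c(script, "compute", "--measurements",
                       tempfile(), "--registry", tempfile(),
                       "--out", out), stdout = TRUE, stderr = TRUE))
  expect_identical(attr(s3, "status"), 2L)
})
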