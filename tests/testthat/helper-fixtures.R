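# In-code fixture builders shared across the suite.

# Quick ExposureExperiment from a named concentration matrix (NA = absent,
# censored entries given separately).
ee_from_matrix <- function(conc, censored = NULL, chem_class = "VOC",
                           tvoc_included = TRUE, cas = NULL,
                           salon = NULL, worker = NULL) {
  conc <- as.matrix(conc)
  n_chem <- nrow(conc)
  n_samp <- ncol(conc)
  chem_names <- rownames(conc)
  if (is.null(chem_names)) chem_names <- sprintf("chem%03d", seq_len(n_chem))
  rownames(conc) <- chem_names
  if (is.null(cas)) cas <- rep("NA", n_chem)
  if (is.null(salon)) salon <- rep("s1", n_samp)
  if (is.null(worker)) worker <- sprintf("h%d", seq_len(n_samp))
  ExposureExperiment(
    concentration = conc, censored = censored,
    chemicals = data.frame(name = chem_names, cas = cas,
                           chem_class = rep_len(chem_class, n_chem),
                           tvoc_included = rep_len(tvoc_included, n_chem)),
    samples = data.frame(salon_id = salon, worker_id = worker,
                         duration_min = 176))
}

# Registry where every listed chemical has a chronic RV.
registry_rv <- function(names, values, cas = NULL) {
  if (is.null(cas)) cas <- rep("NA", length(names))
  ReferenceRegistry(data.frame(chemical = names, cas = cas, rv = values,
                               rv_source = rep("test", length(names))))
}

# Write a measurements CSV from a data.frame of rows.
write_measurements_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  path
}

measurement_row <- function(salon = "s1", worker = "h1", chemical = "x",
                            cas = "NA", chem_class = "VOC", conc = "10",
                            duration = "176") {
  data.frame(salon_id = salon, worker_id = worker, duration_min = duration,
             chemical = chemical, cas = cas, chem_class = chem_class,
             concentration = as.character(conc))
}

# A RiskAssessment whose hazard quotients equal the given per-chemical
# concentrations (all reference values 1), one sample per list element.
risk_from_hqs <- function(hq_list, salon = NULL) {
  chems <- sort(unique(unlist(lapply(hq_list, names))))
  conc <- matrix(NA_real_, length(chems), length(hq_list),
                 dimnames = list(chems, NULL))
  for (j in seq_along(hq_list)) conc[names(hq_list[[j]]), j] <- hq_list[[j]]
  ee <- ee_from_matrix(conc, salon = salon)
  suppressWarnings(suppressMessages(
    hazardIndex(ee, registry_rv(chems, rep(1, length(chems))))))
}
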