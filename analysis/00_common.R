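# Shared setup for the numbered analysis drivers: one deterministic
# synthetic study population (the generator's defaults emulate the target
# cohort: two sexes, ~18% diabetes, admixed ancestry, competing causes of
# death), passed through the exclusion cascade, with both allele scores and
# principal components ready for the estimators. Every driver rebuilds it
# from the same seed, so the scripts can run independently and still agree.

library(mrsurv)

ANALYSIS_SEED <- 20260924L
ANALYSIS_N <- 30000L

build_study <- function(n = ANALYSIS_N, seed = ANALYSIS_SEED, ...) {
  params <- sim_params(n_individuals = n, seed = seed, ...)
  sim <- simulate_cohort(params)
  ex <- apply_exclusions(sim$cohort, sim$flags)
  cohort <- ex$analysis
  keep <- match(cohort$individual_id, sim$cohort$individual_id)
  dos <- sim$dosages[keep, , drop = FALSE]
  attr(dos, "counted_allele") <- attr(sim$dosages, "counted_allele")
  panel_bmi <- sim$panel[sim$panel$trait == "bmi", ]
  panel_diab <- sim$panel[sim$panel$trait == "diabetes", ]
  list(params = params, sim = sim, ledger = ex$ledger, cohort = cohort,
       dosages = dos, panel_bmi = panel_bmi, panel_diab = panel_diab,
       score_bmi = compute_score(dos, panel_bmi)$std_score,
       score_diab = compute_score(dos, panel_diab)$std_score,
       pcs = cohort[, c("pc1", "pc2")],
       exposure = cohort$bmi_measured,
       records = cohort[, c("entry_age", "exit_age", "died", "cause")])
}

save_table <- function(df, name) {
  dir.create("results", showWarnings = FALSE)
  path <- file.path("results", paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
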