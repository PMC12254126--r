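# Is the BMI-mortality relation log-linear? Residual and doubly ranked
# stratification, per-stratum Wald ratios over the stratum mean exposure,
# heterogeneity and trend tests, and the age/sex negative controls that
# probe the stratification itself for selection distortion.

source(file.path("analysis", "00_common.R"))

study <- build_study()
ch <- study$cohort
q <- 10

for (method in c("residual", "doubly_ranked")) {
  st <- if (method == "residual")
    residual_strata(study$exposure, study$score_bmi,
                    covariates = study$pcs, q = q)
  else doubly_ranked_strata(study$exposure, study$score_bmi, q = q)
  nl <- stratum_mr(st, ch, study$score_bmi, study$exposure,
                   covariates = study$pcs)
  message(sprintf("%s: Q p=%.3f, trend p=%.3f over %d strata", method,
                  nl$heterogeneity$p, nl$trend$p, nrow(nl$table)))
  save_table(cbind(method = method, nl$table), paste0("strata_", method))
  if (method == "doubly_ranked") {
    nc_age <- negative_control(st, study$score_bmi, ch$entry_age, "age")
    nc_sex <- negative_control(st, study$score_bmi, ch$sex, "sex")
    save_table(cbind(control = "entry_age", nc_age), "negative_control_age")
    save_table(cbind(control = "sex", nc_sex), "negative_control_sex")
    message(sprintf("negative controls: max |z| age %.2f, sex %.2f",
                    max(abs(nc_age$z)), max(abs(nc_sex$z))))
  }
}
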