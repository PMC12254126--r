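# Small-cohort parameter presets used throughout the suite: reduced panels
# and two stored PCs keep each simulated fixture under a second.
small_params <- function(n = 4000, seed = 1L, ...) {
  args <- list(n_individuals = n, n_variants_bmi = 80, n_variants_diab = 40,
               n_pcs = 2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_params, args)
}

# Simulate a cohort and precompute the pieces most tests need.
sim_fixture <- function(params) {
  sim <- simulate_cohort(params)
  ch <- sim$cohort
  pb <- sim$panel[sim$panel$trait == "bmi", ]
  pd <- sim$panel[sim$panel$trait == "diabetes", ]
  list(sim = sim, cohort = ch,
       panel_bmi = pb, panel_diab = pd,
       score_bmi = compute_score(sim$dosages, pb)$std_score,
       score_diab = compute_score(sim$dosages, pd)$std_score,
       pcs = ch[, grep("^pc", names(ch)), drop = FALSE],
       records = ch[, c("entry_age", "exit_age", "died", "cause")])
}

# Parametric summary-statistic generator for the two-sample estimators:
# beta_zx ~ N(mu, se_zx^2) around positive per-allele effects, beta_zy =
# slope * mu + pleio + N(0, se_zy^2).
make_summaries <- function(k = 30, slope = 0.1, pleio = 0, se_zx = 0.01,
                           se_zy = 0.02, mu_range = c(0.05, 0.3)) {
  mu <- runif(k, mu_range[1], mu_range[2])
  pl <- if (length(pleio) == 1) rep(pleio, k) else pleio
  harmonize_summaries(data.frame(
    variant_id = sprintf("v%03d", seq_len(k)),
    beta_zx = rnorm(k, mu, se_zx), se_zx = se_zx,
    beta_zy = slope * mu + pl + rnorm(k, 0, se_zy), se_zy = se_zy,
    stringsAsFactors = FALSE))
}
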