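test_that("dosage variance matches the Hardy-Weinberg form 2p(1-p)", {
  p <- small_params(n = 20000, ancestry_freq_shift = 0)
  pan <- simulate_panel(p)
  g <- simulate_genotypes(pan, p)
  v_emp <- apply(g$dosages, 2, var)
  v_hwe <- 2 * pan$allele_freq * (1 - pan$allele_freq)
  expect_lt(max(abs(v_emp - v_hwe) / v_hwe), 0.10)
  expect_lt(mean(abs(v_emp - v_hwe) / v_hwe), 0.03)
  # hard-call dosages are allele counts
  expect_true(all(g$dosages %in% c(0, 1, 2)))
})

test_that("panel weights give the raw score unit variance under HWE", {
  p <- small_params(n = 20000, ancestry_freq_shift = 0)
  pan <- simulate_panel(p)
  pb <- pan[pan$trait == "bmi", ]
  expect_equal(sum(pb$weight^2 * 2 * pb$allele_freq * (1 - pb$allele_freq)),
               1, tolerance = 1e-12)
  g <- simulate_genotypes(pan, p)
  raw <- as.numeric(g$dosages[, pb$variant_id] %*% pb$weight)
  expect_equal(var(raw), 1, tolerance = 0.1)
  # a zero-weight variant contributes nothing
  pb0 <- pb[1, ]; pb0$weight <- 0
  s <- compute_score(g$dosages, pb0)
  expect_true(all(s$raw_score == 0))
})

test_that("the two trait panels are disjoint and ids unique", {
  pan <- simulate_panel(small_params())
  expect_false(anyDuplicated(pan$variant_id) > 0)
  expect_length(intersect(pan$variant_id[pan$trait == "bmi"],
                          pan$variant_id[pan$trait == "diabetes"]), 0)
})

test_that("ancestry-frequency shift drives PC1; no shift, no structure", {
  p0 <- small_params(n = 5000, ancestry_freq_shift = 0, seed = 3)
  g0 <- simulate_genotypes(simulate_panel(p0), p0)
  expect_lt(abs(cor(g0$pcs[, 1], g0$ancestry)), 0.1)
  # default shift with the default-size panel
  p1 <- sim_params(n_individuals = 5000, n_variants_diab = 40, n_pcs = 2,
                   seed = 3)
  g1 <- simulate_genotypes(simulate_panel(p1), p1)
  expect_gt(abs(cor(g1$pcs[, 1], g1$ancestry)), 0.9)
  # ancestry proportion distribution: median near 0.67
  expect_equal(median(g1$ancestry), 0.67, tolerance = 0.03)
})

test_that("phenotypes hit the calibration targets", {
  p <- small_params(n = 20000, seed = 5)
  fx <- sim_fixture(p)
  ch <- fx$cohort
  m <- tapply(ch$bmi_measured, ch$sex, mean)
  s <- tapply(ch$bmi_measured, ch$sex, sd)
  expect_equal(unname(m["male"]), 28.0, tolerance = 0.3)
  expect_equal(unname(m["female"]), 29.7, tolerance = 0.3)
  expect_equal(unname(s["male"]), 4.2, tolerance = 0.5)
  expect_equal(unname(s["female"]), 5.2, tolerance = 0.5)
  prev <- mean(ch$diabetes != "none")
  expect_equal(prev, 0.18, tolerance = 0.02)
  expect_equal(mean(ch$diabetes == "diagnosed") / prev, 13 / 18,
               tolerance = 0.05)
})

test_that("zero weight-loss delta leaves measured BMI at truth plus noise", {
  p <- small_params(n = 5000, reverse_causality_delta = 0, bmi_meas_sd = 0.3)
  fx <- sim_fixture(p)
  d <- fx$cohort$bmi_measured - fx$cohort$bmi_true
  expect_equal(mean(d), 0, tolerance = 0.02)
  expect_equal(sd(d), 0.3, tolerance = 0.02)
  # with the delta on, diagnosed diabetics sit ~delta below their truth
  p2 <- small_params(n = 5000, bmi_meas_sd = 0.3)
  fx2 <- sim_fixture(p2)
  dd <- with(fx2$cohort, (bmi_measured - bmi_true)[diabetes == "diagnosed"])
  expect_equal(mean(dd), -p2$reverse_causality_delta, tolerance = 0.05)
})

test_that("marginal Cox on latent BMI recovers the direct-only hazard", {
  p <- small_params(n = 20000, mediated_fraction = 0, confounder_loghr = 0,
                    causal_loghr_per_unit = 0.10, seed = 9)
  fx <- sim_fixture(p)
  fit <- fit_cox(fx$records, data.frame(bmi = fx$cohort$bmi_true),
                 window = NULL)
  expect_lt(abs(fit$beta_zy - 0.10), 2 * fit$se_zy)
})

test_that("cause labels roll up additively and match the death indicator", {
  fx <- sim_fixture(small_params(n = 5000, seed = 2))
  ch <- fx$cohort
  expect_true(all((ch$cause == "none") == !ch$died))
  ru <- cause_rollup(ifelse(ch$died, ch$cause, NA))
  tot <- ru$n_events[ru$cause == "all"]
  expect_identical(tot, sum(ch$died))
  leaves <- sum(ru$n_events[ru$cause %in% cause_leaves()])
  expect_identical(leaves, tot)
  vm <- ru$n_events[ru$cause == "vascular_metabolic"]
  nvm <- ru$n_events[ru$cause == "nonvascular_metabolic"]
  expect_identical(vm + nvm, tot)
  expect_identical(ru$n_events[ru$cause == "vascular"],
                   sum(ru$n_events[ru$cause %in%
                                     c("cardiac", "cerebrovascular",
                                       "other_vascular")]))
  expect_true(all(ch$exit_age > ch$entry_age))
})

test_that("identical parameters replay byte-identically", {
  p <- small_params(n = 1000, seed = 77)
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(p)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$dosages, s2$dosages)
  expect_identical(s1$flags, s2$flags)
})

test_that("exclusion cascade counts each individual at its first failure", {
  cohort <- data.frame(individual_id = sprintf("i%02d", 1:10),
                       entry_age = c(40, 50, 60, 70, 45, 55, 65, 80, 50, 40))
  f <- function(...) {
    m <- matrix(FALSE, 10, 4,
                dimnames = list(NULL, c("qc_fail", "age_ge_90",
                                        "implausible_anthropometry",
                                        "uncertain_linkage")))
    for (x in list(...)) m[x[1], x[2]] <- TRUE
    cbind(data.frame(individual_id = cohort$individual_id),
          as.data.frame(m))
  }
  # one failing each successive flag
  flags <- f(c(1, 1), c(2, 2), c(3, 3), c(4, 4))
  ex <- apply_exclusions(cohort, flags)
  expect_equal(ex$ledger$n_removed, c(1, 1, 1, 1))
  expect_equal(nrow(ex$analysis) + nrow(ex$older), 6)
  expect_equal(nrow(ex$older), 1)  # the entry-age-80 row
  # dual failure counted once, at the first step
  flags2 <- f(c(1, 1), c(1, 2))
  ex2 <- apply_exclusions(cohort, flags2)
  expect_equal(ex2$ledger$n_removed, c(1, 0, 0, 0))
  # no flags: ledger all zeros, set unchanged
  ex0 <- apply_exclusions(cohort, f())
  expect_equal(ex0$ledger$n_removed, rep(0, 4))
  expect_equal(nrow(ex0$analysis) + nrow(ex0$older), 10)
  # percentages replay from counts to 1 decimal
  expect_equal(ex$ledger$pct_of_initial,
               round(100 * ex$ledger$n_removed / 10, 1))
  expect_error(apply_exclusions(cohort, cbind(f(), bogus = TRUE)),
               "unknown exclusion flag")
})
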