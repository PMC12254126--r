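test_that("per-variant summaries match a direct refit and harmonize", {
  fx <- sim_fixture(small_params(n = 200, n_variants_bmi = 80, seed = 33))
  dos <- fx$sim$dosages[, fx$panel_bmi$variant_id[1:5], drop = FALSE]
  poly <- apply(dos, 2, sd) > 0
  summ <- per_snp_summaries(dos[, poly, drop = FALSE],
                            fx$cohort$bmi_measured, fx$records,
                            window = NULL)
  expect_true(all(summ$beta_zx >= 0))
  # brute-force oracle: plain lm / coxph on the same rows
  v <- summ$variant_id[1]
  d <- dos[, v]
  ml <- lm(fx$cohort$bmi_measured ~ d)
  ev <- fx$records$died
  mc <- survival::coxph(survival::Surv(fx$records$entry_age,
                                       fx$records$exit_age, ev) ~ d,
                        ties = "efron")
  sgn <- if (coef(ml)[["d"]] < 0) -1 else 1
  expect_equal(summ$beta_zx[summ$variant_id == v],
               sgn * unname(coef(ml)["d"]), tolerance = 1e-8)
  expect_equal(summ$beta_zy[summ$variant_id == v],
               sgn * unname(coef(mc)["d"]), tolerance = 1e-8)
  # allele-flip invariance after harmonization
  dos_fl <- dos
  dos_fl[, v] <- 2 - dos_fl[, v]
  summ_fl <- per_snp_summaries(dos_fl[, poly, drop = FALSE],
                               fx$cohort$bmi_measured, fx$records,
                               window = NULL)
  expect_equal(summ_fl$beta_zx, summ$beta_zx, tolerance = 1e-8)
  expect_equal(summ_fl$beta_zy, summ$beta_zy, tolerance = 1e-8)
  # monomorphic variants are dropped with a warning
  dos_m <- dos
  dos_m[, 2] <- 1
  expect_warning(s2 <- per_snp_summaries(dos_m, fx$cohort$bmi_measured,
                                         fx$records, window = NULL),
                 "monomorphic")
  expect_false(colnames(dos_m)[2] %in% s2$variant_id)
})

test_that("IVW through the origin matches a brute-force minimizer", {
  summ <- data.frame(beta_zx = c(0.1, 0.2, 0.15, 0.3, 0.25),
                     se_zx = 0.01,
                     beta_zy = c(0.011, 0.019, 0.016, 0.032, 0.024),
                     se_zy = c(0.002, 0.003, 0.004, 0.002, 0.005))
  est <- ivw_2s(summ)
  grid <- seq(0, 0.3, by = 1e-5)
  w <- 1 / summ$se_zy^2
  loss <- vapply(grid, function(g)
    sum(w * (summ$beta_zy - g * summ$beta_zx)^2), numeric(1))
  expect_equal(est$beta_iv, grid[which.min(loss)], tolerance = 5e-4)
  # exact shared ratio: estimate r with Q = 0
  summ_r <- data.frame(beta_zx = c(0.1, 0.2, 0.3), se_zx = 0.01,
                       beta_zy = 0.5 * c(0.1, 0.2, 0.3), se_zy = 0.01)
  est_r <- ivw_2s(summ_r)
  expect_equal(est_r$beta_iv, 0.5, tolerance = 1e-12)
  expect_equal(attr(est_r, "Q"), 0, tolerance = 1e-20)
  # a dominant-precision variant carries the estimate
  summ_d <- data.frame(beta_zx = c(0.2, 0.1, 0.1), se_zx = 0.01,
                       beta_zy = c(0.08, 0.001, -0.002),
                       se_zy = c(1e-4, 0.5, 0.5))
  expect_equal(ivw_2s(summ_d)$beta_iv, 0.4, tolerance = 1e-3)
})

test_that("weighted median interpolates the 50% cumulative-weight ratio", {
  # equal weights, ratios 1..5: the plain median
  summ <- data.frame(beta_zx = 1, se_zx = 1e-6, beta_zy = 1:5, se_zy = 1)
  expect_equal(mrsurv:::weighted_median_point(summ$beta_zy / summ$beta_zx,
                                              (summ$beta_zx / summ$se_zy)^2),
               3)
  # a variant holding virtually all weight drives the estimate
  r <- c(1, 2, 3)
  w <- c(0.995, 0.0025, 0.0025)
  expect_equal(mrsurv:::weighted_median_point(r, w), 1, tolerance = 0.01)
  # 7-variant fixture vs an independent cumulative-weight scan
  set.seed(101)
  r7 <- sort(rnorm(7, 0.5, 0.3)); w7 <- runif(7)
  est <- mrsurv:::weighted_median_point(r7, w7)
  wn <- w7 / sum(w7)
  cum <- cumsum(wn) - wn / 2
  k <- which(cum >= 0.5)[1]
  oracle <- r7[k - 1] + (r7[k] - r7[k - 1]) *
    (0.5 - cum[k - 1]) / (cum[k] - cum[k - 1])
  expect_equal(est, oracle, tolerance = 1e-12)
  # the exported estimator is seeded and reproducible
  summ7 <- data.frame(beta_zx = abs(rnorm(7, 0.2, 0.05)), se_zx = 0.01,
                      beta_zy = rnorm(7, 0.02, 0.01), se_zy = 0.01)
  wm1 <- weighted_median(summ7, n_boot = 200, seed = 3)
  wm2 <- weighted_median(summ7, n_boot = 200, seed = 3)
  expect_identical(wm1$beta_iv, wm2$beta_iv)
  expect_identical(wm1$se_iv, wm2$se_iv)
  expect_error(weighted_median(summ7[1:2, ]))
})

test_that("Egger regression separates slope from directional pleiotropy", {
  set.seed(111)
  # constant pleiotropy shifts the intercept, not the slope
  s0 <- make_summaries(k = 50, slope = 0.1, pleio = 0, se_zy = 0.005)
  sc <- s0
  sc$beta_zy <- sc$beta_zy + 0.02
  e0 <- mr_egger(s0)
  ec <- mr_egger(sc)
  expect_equal(ec$intercept - e0$intercept, 0.02, tolerance = 1e-10)
  expect_equal(ec$slope$beta_iv, e0$slope$beta_iv, tolerance = 1e-10)
  expect_lt(abs(ec$intercept - 0.02), 3 * ec$intercept_se)
  expect_lt(abs(ec$slope$beta_iv - 0.1), 3 * ec$slope$se_iv)
  expect_true(ec$i2_gx >= 0 && ec$i2_gx <= 1)
  # null calibration of the intercept test
  hits <- 0
  for (r in 1:50) {
    s <- make_summaries(k = 40, slope = 0.1, pleio = 0)
    e <- mr_egger(s)
    if (abs(e$intercept) < 2 * e$intercept_se) hits <- hits + 1
  }
  expect_gte(hits, 45)
  # refusals: too few variants, no spread
  expect_error(mr_egger(s0[1:2, ]))
  s_flat <- s0; s_flat$beta_zx <- 0.2
  expect_error(mr_egger(s_flat), "spread")
})

test_that("weighted median resists 30% directional pleiotropy, IVW drifts", {
  set.seed(121)
  drift <- 0; robust <- 0
  for (r in 1:20) {
    k <- 40
    bad <- seq_len(k) <= 12   # 30% invalid, all shifted upward
    s <- make_summaries(k = k, slope = 0.1,
                        pleio = ifelse(bad, 0.03, 0), se_zy = 0.005)
    wm <- weighted_median(s, n_boot = 120, seed = r)
    iv <- ivw_2s(s)
    if (abs(wm$beta_iv - 0.1) < 2 * wm$se_iv) robust <- robust + 1
    if (iv$beta_iv - 0.1 > 2 * iv$se_iv) drift <- drift + 1
  }
  expect_gte(robust, 16)
  expect_gte(drift, 16)
})
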