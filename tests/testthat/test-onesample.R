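zy_fit <- function(beta, se) list(beta_zy = beta, se_zy = se,
                                  cause = "all", label = "test")
zx_fit <- function(beta, se, f = 1000) list(beta_zx = beta, se_zx = se,
                                            f_statistic = f)

test_that("Wald ratio matches the headline scaling conventions", {
  # zero numerator: null estimate, HR per 5 exactly 1
  w0 <- wald_ratio(zy_fit(0, 0.02), zx_fit(1, 0.01))
  expect_equal(w0$beta_iv, 0)
  expect_equal(w0$hr_scaled, 1)
  # the reporting identity: 0.1176 per unit is ~1.80 per 5 kg/m2
  w1 <- wald_ratio(zy_fit(0.1176, 0.02), zx_fit(1, 1e-9))
  expect_equal(w1$hr_scaled, exp(5 * 0.1176), tolerance = 1e-12)
  expect_equal(round(w1$hr_scaled, 2), 1.80)
  # CI construction
  expect_equal(w1$ci_lo, exp(5 * (w1$beta_iv - qnorm(0.975) * w1$se_iv)),
               tolerance = 1e-10)
  # weak instruments are flagged, not suppressed
  wf <- wald_ratio(zy_fit(0.1, 0.02), zx_fit(0.5, 0.3, f = 3))
  expect_true("weak_instrument" %in% wf$flags)
  expect_error(wald_ratio(zy_fit(0.1, 0.02), zx_fit(0, 0.01)), "zero")
})

test_that("delta-method SE matches Monte-Carlo ratio propagation", {
  zy <- zy_fit(0.08, 0.02); zx <- zx_fit(0.8, 0.04)
  w <- wald_ratio(zy, zx)
  set.seed(51)
  draws <- rnorm(1e5, zy$beta_zy, zy$se_zy) / rnorm(1e5, zx$beta_zx,
                                                    zx$se_zx)
  expect_lt(abs(w$se_iv - sd(draws)) / sd(draws), 0.05)
})

test_that("IVW pooling is the precision-weighted least-squares solution", {
  e1 <- causal_estimate(0.10, 0.05)
  # single estimate unchanged
  p1 <- ivw_pool(list(e1))
  expect_equal(p1$beta_iv, 0.10)
  expect_equal(p1$se_iv, 0.05)
  # duplicate halves the variance
  p2 <- ivw_pool(list(e1, e1))
  expect_equal(p2$beta_iv, 0.10)
  expect_equal(p2$se_iv, 0.05 / sqrt(2))
  # three-estimate fixture vs a grid-search minimizer of sum w (b - bi)^2
  b <- c(0.05, 0.12, 0.20); s <- c(0.02, 0.05, 0.08)
  p3 <- ivw_pool(list(causal_estimate(b[1], s[1]),
                      causal_estimate(b[2], s[2]),
                      causal_estimate(b[3], s[3])))
  grid <- seq(0, 0.3, by = 1e-5)
  loss <- vapply(grid, function(g) sum((g - b)^2 / s^2), numeric(1))
  expect_equal(p3$beta_iv, grid[which.min(loss)], tolerance = 2e-5)
  # permutation invariance and scale consistency
  p3r <- ivw_pool(list(causal_estimate(b[3], s[3]),
                       causal_estimate(b[1], s[1]),
                       causal_estimate(b[2], s[2])))
  expect_equal(p3$beta_iv, p3r$beta_iv)
  p3c <- ivw_pool(list(causal_estimate(3 * b[1], 3 * s[1]),
                       causal_estimate(3 * b[2], 3 * s[2]),
                       causal_estimate(3 * b[3], 3 * s[3])))
  expect_equal(p3c$beta_iv, 3 * p3$beta_iv, tolerance = 1e-12)
  # mixed report scales refuse
  expect_error(ivw_pool(list(e1, causal_estimate(0.1, 0.05,
                                                 report_scale = 1))),
               "report scales")
})

test_that("2SLS agrees with the Wald ratio and exposes stage algebra", {
  fx <- sim_fixture(small_params(n = 8000, seed = 23))
  ts <- tsls_estimate(data.frame(s = fx$score_bmi), fx$cohort$bmi_measured,
                      fx$records, covariates = NULL)
  s1 <- attr(ts, "stage1")
  # predicted-exposure SD equals |beta_zx| for a lone standardized score
  expect_equal(sd(s1$fitted), abs(unname(s1$coef["s"])), tolerance = 1e-6)
  zx <- instrument_strength(fx$score_bmi, fx$cohort$bmi_measured)
  zy <- fit_cox(fx$records, fx$score_bmi)
  wd <- wald_ratio(zy, zx)
  # same data, same window: point estimates agree closely
  expect_equal(ts$beta_iv, wd$beta_iv, tolerance = 0.02)
  # in a purely linear system 2SLS and the Wald ratio are identical algebra
  set.seed(61)
  n <- 500
  z <- rnorm(n); xx <- 0.5 * z + rnorm(n); yy <- 0.3 * xx + rnorm(n)
  s1l <- fit_linear(xx, data.frame(z = z))
  s2l <- fit_linear(yy, data.frame(xhat = s1l$fitted))
  wald_lin <- unname(fit_linear(yy, data.frame(z = z))$coef["z"] /
                       s1l$coef["z"])
  expect_equal(unname(s2l$coef["xhat"]), wald_lin, tolerance = 1e-8)
})

test_that("subgroup analysis returns per-level ratios, Q and a trend", {
  fx <- sim_fixture(small_params(n = 12000, seed = 29))
  sg <- subgroup_analysis("age_band", fx$cohort, fx$score_bmi,
                          fx$cohort$bmi_measured, covariates = fx$pcs)
  expect_gte(length(sg$estimates), 2)
  expect_gte(sg$heterogeneity$Q, 0)
  expect_false(is.null(sg$trend))
  # identical estimates give Q exactly 0
  q0 <- cochran_q(c(0.1, 0.1, 0.1), c(0.02, 0.03, 0.05))
  expect_equal(q0$Q, 0)
  # an unordered dimension carries no trend
  sg2 <- subgroup_analysis("district", fx$cohort, fx$score_bmi,
                           fx$cohort$bmi_measured, covariates = fx$pcs)
  expect_null(sg2$trend)
  # subgroup-specific denominators also work
  sg3 <- subgroup_analysis("ancestry_tertile", fx$cohort, fx$score_bmi,
                           fx$cohort$bmi_measured, covariates = fx$pcs,
                           denominator = "subgroup")
  expect_gte(length(sg3$estimates), 2)
})
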