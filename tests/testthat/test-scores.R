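panel_fixture <- function(w = c(0.3, -0.2, 0.5), p = c(0.2, 0.5, 0.7)) {
  data.frame(variant_id = paste0("v", seq_along(w)),
             effect_allele = c("A", "C", "G")[seq_along(w)],
             other_allele = c("G", "T", "A")[seq_along(w)],
             weight = w, allele_freq = p, trait = "bmi",
             stringsAsFactors = FALSE)
}

dosage_fixture <- function(panel, n = 6, seed = 1) {
  set.seed(seed)
  d <- sapply(panel$allele_freq, function(p) rbinom(n, 2, p))
  colnames(d) <- panel$variant_id
  storage.mode(d) <- "double"
  attr(d, "counted_allele") <- setNames(panel$effect_allele,
                                        panel$variant_id)
  d
}

test_that("raw scores are weighted dosage sums on the additive scale", {
  pan <- panel_fixture(w = c(0.4), p = c(0.5))[1, ]
  d <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "v1"))
  s <- compute_score(d, pan)
  expect_equal(s$raw_score, c(0, 0.4, 0.8))
  # all-zero weights give everyone zero
  pan3 <- panel_fixture(w = c(0, 0, 0))
  d3 <- dosage_fixture(pan3)
  expect_true(all(compute_score(d3, pan3)$raw_score == 0))
  # standardized score has mean 0 SD 1 to 1e-8
  pan2 <- panel_fixture()
  d2 <- dosage_fixture(pan2, n = 50)
  s2 <- compute_score(d2, pan2)
  expect_equal(mean(s2$std_score), 0, tolerance = 1e-8)
  expect_equal(sd(s2$std_score), 1, tolerance = 1e-8)
})

test_that("missing dosages are mean-imputed at twice the allele frequency", {
  pan <- panel_fixture()
  d <- dosage_fixture(pan, n = 20)
  d_na <- d; d_na[1, "v2"] <- NA
  s_na <- compute_score(d_na, pan)
  d_imp <- d; d_imp[1, "v2"] <- 2 * pan$allele_freq[2]
  s_imp <- compute_score(d_imp, pan)
  expect_equal(s_na$raw_score, s_imp$raw_score, tolerance = 1e-12)
  # "na" policy propagates instead
  expect_true(is.na(compute_score(d_na, pan, missing_policy = "na")$raw_score[1]))
  # excessive missingness is a hard error
  d_bad <- d; d_bad[1:10, "v2"] <- NA
  expect_error(compute_score(d_bad, pan), "missing dosages")
})

test_that("scores are invariant to variant order and strand flips", {
  pan <- panel_fixture()
  d <- dosage_fixture(pan, n = 30)
  base <- compute_score(d, pan)$raw_score
  # permuted panel columns
  perm <- pan[c(3, 1, 2), ]
  expect_equal(compute_score(d, perm)$raw_score, base)
  # flip one variant: dosage 2-d counted on the other allele
  d_fl <- d
  d_fl[, "v2"] <- 2 - d_fl[, "v2"]
  ca <- attr(d, "counted_allele"); ca["v2"] <- pan$other_allele[2]
  attr(d_fl, "counted_allele") <- ca
  expect_warning(s_fl <- compute_score(d_fl, pan), "flipping")
  expect_equal(s_fl$raw_score, base)
  # unresolvable allele is a hard error
  ca["v2"] <- "T"  # neither effect (C) nor other (T)? other IS T here; use G
  ca["v2"] <- "G"
  attr(d_fl, "counted_allele") <- ca
  expect_error(compute_score(d_fl, pan), "neither effect nor other")
})

test_that("greedy clumping follows the p-value order under the r2 cap", {
  ids <- sprintf("v%02d", 1:10)
  set.seed(4)
  pv <- runif(10)
  # three-block correlation overlay
  r2 <- diag(10); dimnames(r2) <- list(ids, ids)
  blocks <- list(1:4, 5:7, 8:10)
  for (b in blocks) for (i in b) for (j in b) if (i != j)
    r2[i, j] <- 0.8
  vars <- data.frame(variant_id = ids, pvalue = pv)
  kept <- ld_clump(vars, r2, r2_threshold = 0.5)
  # brute-force replay of the greedy rule
  ord <- order(pv, ids)
  exp_keep <- character(0)
  for (v in ids[ord]) if (length(exp_keep) == 0 ||
                          all(r2[v, exp_keep] < 0.5))
    exp_keep <- c(exp_keep, v)
  expect_identical(kept, exp_keep)
  expect_length(kept, 3)  # one per block
  # threshold 1 retains everything; near-zero keeps one per component
  expect_length(ld_clump(vars, r2, r2_threshold = 1.01), 10)
  expect_length(ld_clump(vars, r2 * 0, r2_threshold = 0.5), 10)
  # two perfectly correlated variants: the smaller p-value wins
  r2p <- diag(2); r2p[1, 2] <- r2p[2, 1] <- 1
  dimnames(r2p) <- list(c("a", "b"), c("a", "b"))
  kept2 <- ld_clump(data.frame(variant_id = c("a", "b"),
                               pvalue = c(0.5, 0.01)), r2p, 0.9)
  expect_identical(kept2, "b")
})

test_that("instrument strength reports the partial-F identity", {
  set.seed(8)
  z <- rnorm(200); z <- (z - mean(z)) / sd(z)
  y <- 2 * z
  f <- instrument_strength(z, y)
  expect_equal(f$beta_zx, 2, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # no-covariate identity F = (n-2) R2 / (1 - R2)
  y2 <- 1.5 * z + rnorm(200)
  f2 <- instrument_strength(z, y2)
  expect_equal(f2$f_statistic,
               (f2$n - 2) * f2$r_squared / (1 - f2$r_squared),
               tolerance = 1e-9)
  # permuted score: R2 near zero, F near 1 on average
  reps <- replicate(30, {
    zp <- sample(z)
    instrument_strength(zp, y2)$f_statistic
  })
  expect_lt(mean(reps), 3)
  # matches R's own partial F from an anova decomposition
  cv <- data.frame(age = rnorm(200))
  f3 <- instrument_strength(z, y2, covariates = cv)
  m0 <- lm(y2 ~ age, data = cv)
  m1 <- lm(y2 ~ age + z, data = cv)
  expect_equal(f3$f_statistic, anova(m0, m1)$F[2], tolerance = 1e-8)
  expect_error(instrument_strength(z[1:10], y2[1:10]), "too small")
  expect_warning(
    instrument_strength(z, y2, covariates = data.frame(a = cv$age,
                                                       b = 2 * cv$age)),
    "aliased")
})

test_that("fifths are sex-specific with sensible gradients", {
  set.seed(11)
  n <- 1000
  sex <- factor(sample(c("male", "female"), n, TRUE),
                levels = c("male", "female"))
  score <- rnorm(n)
  chars <- data.frame(const = rep(2.5, n), self = score,
                      indep = rnorm(n))
  tab <- fifths_table(score, sex, chars)
  cst <- tab[tab$characteristic == "const", ]
  expect_true(all(abs(cst$gradient) < 1e-12))
  slf <- tab[tab$characteristic == "self" & tab$sex == "male", ]
  expect_true(all(diff(as.numeric(slf[1, paste0("fifth", 1:5)])) > 0))
  ind <- tab[tab$characteristic == "indep", ]
  expect_true(all(abs(ind$gradient) < 0.4))
  # fifth sizes within sex differ by at most one
  for (s in levels(sex)) {
    i <- sex == s
    r <- rank(score[i], ties.method = "first")
    sz <- table(floor((r - 1) * 5 / sum(i)) + 1)
    expect_lte(diff(range(sz)), 1)
  }
})

test_that("a confounder independent of the score shows a null gradient", {
  fx <- sim_fixture(small_params(n = 8000, seed = 13))
  tab <- fifths_table(fx$score_bmi, fx$cohort$sex,
                      data.frame(confounder = fx$cohort$confounder,
                                 bmi = fx$cohort$bmi_measured,
                                 diabetes = fx$cohort$diabetes != "none"))
  conf <- tab[tab$characteristic == "confounder", ]
  expect_true(all(abs(conf$gradient) < 0.15))
  # variables downstream of the exposure rise across fifths
  expect_true(all(tab$gradient[tab$characteristic == "bmi"] > 0))
  expect_true(all(tab$gradient[tab$characteristic == "diabetes"] > 0))
})
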