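#' Simulate the instrument panels (BMI score and diabetes-liability score)
#'
#' Draws two disjoint variant panels with allele frequencies on (0.05, 0.95)
#' and normal per-allele weights rescaled so each raw score has unit variance
#' under Hardy-Weinberg dosage variance 2p(1-p). Weights are therefore in
#' score-SD units; the phenotype model maps score SDs to kg/m2 through the
#' per-sex slope, which pins the implied score-on-exposure R-squared at
#' \code{target_r2}.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return data.frame of class \code{"variant_panel"} with columns
#'   \code{variant_id}, \code{effect_allele}, \code{other_allele},
#'   \code{weight}, \code{allele_freq}, \code{trait}.
#' @export
simulate_panel <- function(params) {
  validate_sim_params(params)
  set.seed(substream_seed(params$seed, "panel"))
  one_panel <- function(m, trait) {
    p <- stats::runif(m, 0.05, 0.95)
    w <- stats::rnorm(m)
    v <- sum(w^2 * 2 * p * (1 - p))
    if (v > 0) w <- w / sqrt(v)  # unit raw-score variance under HWE
    al <- t(vapply(seq_len(m), function(i) sample(c("A", "C", "G", "T"), 2),
                   character(2)))
    data.frame(
      variant_id = sprintf("snp_%s_%04d", trait, seq_len(m)),
      effect_allele = al[, 1], other_allele = al[, 2],
      weight = w, allele_freq = p, trait = trait,
      stringsAsFactors = FALSE
    )
  }
  panel <- rbind(one_panel(params$n_variants_bmi, "bmi"),
                 one_panel(params$n_variants_diab, "diabetes"))
  if (anyDuplicated(panel$variant_id)) stop("variant ids must be unique")
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

#' Simulate genotype dosages with ancestry-linked allele frequencies
#'
#' Each individual draws an admixture proportion from a Beta distribution;
#' each variant's frequency shifts linearly with ancestry (random per-variant
#' sign), so the leading principal component of the centred dosage matrix
#' tracks ancestry. Principal components are deterministic functions of the
#' genotypes (eigenvectors of the variant covariance, sign-fixed), so
#' adjusting for them absorbs the ancestry confounding the generator plants.
#'
#' @param panel a variant panel from \code{\link{simulate_panel}}.
#' @param params a \code{\link{sim_params}} object.
#' @return list with \code{dosages} (n x m matrix, columns named by variant,
#'   counted allele recorded in \code{attr(,"counted_allele")}),
#'   \code{ancestry} (per-individual admixture proportion) and \code{pcs}
#'   (n x \code{n_pcs} matrix).
#' @export
simulate_genotypes <- function(panel, params) {
  validate_sim_params(params)
  n <- params$n_individuals
  m <- nrow(panel)
  set.seed(substream_seed(params$seed, "genotypes"))
  anc <- stats::rbeta(n, params$ancestry_shape[1], params$ancestry_shape[2])
  anc_mean <- params$ancestry_shape[1] / sum(params$ancestry_shape)

  sgn <- sample(c(-1, 1), m, replace = TRUE)
  shift <- sgn * params$ancestry_freq_shift *
    2 * pmin(panel$allele_freq, 1 - panel$allele_freq)
  pmat <- outer(anc - anc_mean, shift) +
    matrix(panel$allele_freq, n, m, byrow = TRUE)
  pmat[pmat < 0.01] <- 0.01
  pmat[pmat > 0.99] <- 0.99
  g <- matrix(stats::rbinom(n * m, 2L, pmat), n, m)
  if (params$dosage_mode == "noisy") {
    g <- pmin(2, pmax(0, g + stats::rnorm(n * m, 0, 0.05)))
  }
  storage.mode(g) <- "double"
  colnames(g) <- panel$variant_id
  attr(g, "counted_allele") <- stats::setNames(panel$effect_allele,
                                               panel$variant_id)
  pcs <- genotype_pcs(g, params$n_pcs)
  list(dosages = g, ancestry = anc, pcs = pcs)
}

# Top principal components of the centred dosage matrix via the m x m
# variant covariance (n >> m here). Sign convention: the largest-magnitude
# loading of each component is positive, so replays are byte-identical.
genotype_pcs <- function(dosages, n_pcs) {
  n <- nrow(dosages)
  mu <- colMeans(dosages)
  x <- sweep(dosages, 2L, mu)
  cc <- crossprod(x) / (n - 1)
  ev <- eigen(cc, symmetric = TRUE)
  k <- min(n_pcs, ncol(x))
  vec <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  pcs <- x %*% vec
  colnames(pcs) <- paste0("pc", seq_len(k))
  pcs
}

#' Simulate phenotypes: BMI, diabetes, covariates
#'
#' Lifelong (latent) BMI combines a sex intercept, the sex-specific genetic
#' component (slope per SD of the BMI score), an ancestry effect, a latent
#' standard-normal confounder shared with the mortality model, and noise;
#' residual variance is set so the score explains \code{target_r2} of
#' measured-BMI variance within each sex. Diabetes arises from a probit
#' liability loading on standardized lifelong BMI and on the disjoint
#' diabetes score, thresholded at the target prevalence; a fixed fraction of
#' diabetes is "diagnosed". Measured BMI subtracts the reverse-causality
#' weight-loss delta for diagnosed diabetes and adds measurement noise.
#'
#' @param geno output of \code{\link{simulate_genotypes}}.
#' @param panel the variant panel (both traits).
#' @param params a \code{\link{sim_params}} object.
#' @return data.frame (one row per individual): ids, sex, entry age, latent
#'   and measured BMI, diabetes status (\code{none}/\code{undiagnosed}/
#'   \code{diagnosed}), ancestry, PCs, district, smoking, activity, the
#'   latent confounder, and the standardized true scores used internally
#'   (columns \code{score_bmi}, \code{score_diab}).
#' @export
simulate_phenotypes <- function(geno, panel, params) {
  validate_sim_params(params)
  n <- params$n_individuals
  if (nrow(geno$dosages) != n) stop("dosage matrix does not match params")
  set.seed(substream_seed(params$seed, "phenotypes"))

  raw <- function(tr) {
    idx <- panel$trait == tr
    as.numeric(geno$dosages[, panel$variant_id[idx], drop = FALSE] %*%
                 panel$weight[idx])
  }
  s_bmi <- as.numeric(scale(raw("bmi")))
  s_diab <- as.numeric(scale(raw("diabetes")))

  sex <- factor(ifelse(stats::runif(n) < params$prop_male, "male", "female"),
                levels = c("male", "female"))
  slope <- params$slope_by_sex[as.character(sex)]
  mu <- params$mean_bmi_by_sex[as.character(sex)]
  sd_tot <- params$slope_by_sex / sqrt(params$target_r2)

  anc_mean <- params$ancestry_shape[1] / sum(params$ancestry_shape)
  anc_var <- prod(params$ancestry_shape) /
    (sum(params$ancestry_shape)^2 * (sum(params$ancestry_shape) + 1))
  resid_var <- sd_tot^2 - params$slope_by_sex^2 -
    params$ancestry_bmi_effect^2 * anc_var -
    params$confounder_strength^2 - params$bmi_meas_sd^2
  if (any(resid_var <= 0))
    stop("generation abort: BMI variance budget exhausted; ",
         "reduce confounder/ancestry effects or target_r2", call. = FALSE)

  confounder <- stats::rnorm(n)
  bmi_true <- mu + slope * s_bmi +
    params$ancestry_bmi_effect * (geno$ancestry - anc_mean) +
    params$confounder_strength * confounder +
    stats::rnorm(n, 0, sqrt(resid_var[as.character(sex)]))

  # probit liability, unit variance by construction
  z_bmi <- (bmi_true - mu) / sd_tot[as.character(sex)]
  e_sd <- sqrt(1 - params$liab_bmi^2 - params$liab_score^2)
  liab <- params$liab_bmi * z_bmi + params$liab_score * s_diab +
    stats::rnorm(n, 0, e_sd)
  tau <- stats::qnorm(1 - params$diabetes_prevalence)
  any_diab <- liab > tau
  diagnosed <- any_diab & stats::runif(n) < params$diagnosed_fraction
  diabetes <- factor(ifelse(!any_diab, "none",
                            ifelse(diagnosed, "diagnosed", "undiagnosed")),
                     levels = c("none", "undiagnosed", "diagnosed"))

  bmi_measured <- bmi_true -
    params$reverse_causality_delta * (diabetes == "diagnosed") +
    stats::rnorm(n, 0, params$bmi_meas_sd)
  bmi_measured <- pmax(bmi_measured, 10)

  entry_age <- rtruncnorm(n, params$entry_age_mean, params$entry_age_sd,
                          params$entry_age_range)
  if (params$entry_age_score_shift != 0) {
    # planted selection defect: recruitment age depends on the instrument
    entry_age <- pmin(pmax(entry_age + params$entry_age_score_shift * s_bmi,
                           params$entry_age_range[1]),
                      params$entry_age_range[2] - 1e-6)
  }

  out <- data.frame(
    individual_id = sprintf("id%06d", seq_len(n)),
    sex = sex,
    entry_age = entry_age,
    bmi_true = bmi_true,
    bmi_measured = bmi_measured,
    diabetes = diabetes,
    ancestry_prop = geno$ancestry,
    district = factor(ifelse(stats::runif(n) < 0.39, "A", "B")),
    smoking = factor(sample(c("never", "former", "current"), n, TRUE,
                            prob = c(0.47, 0.20, 0.33)),
                     levels = c("never", "former", "current")),
    activity = factor(ifelse(stats::runif(n) < 0.22, "any", "none"),
                      levels = c("none", "any")),
    confounder = confounder,
    score_bmi = s_bmi,
    score_diab = s_diab,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(geno$pcs))
}

rtruncnorm <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

# Average marginal effect of 1 kg/m2 of lifelong BMI on P(any diabetes),
# under the unit-variance probit liability: phi(tau) * load / sd(BMI),
# averaged over the sex mix.
diabetes_marginal_effect <- function(params) {
  tau <- stats::qnorm(1 - params$diabetes_prevalence)
  sd_tot <- params$slope_by_sex / sqrt(params$target_r2)
  inv_sd <- params$prop_male / sd_tot["male"] +
    (1 - params$prop_male) / sd_tot["female"]
  as.numeric(stats::dnorm(tau) * params$liab_bmi * inv_sd)
}

# Hazard coefficients implied by the causal parameters. The total effect
# per kg/m2 splits into a direct term and a diabetes-mediated term. The
# mediated pathway is calibrated on the hazard scale: the marginal
# log-hazard slope contributed by a binary mediator with conditional log HR
# b and prevalence P is m * (e^b - 1) / (1 + P (e^b - 1)), not m * b --
# exponentiation makes a strong binary covariate contribute more to the
# marginal slope than its log HR times the probability slope m.
hazard_coefficients <- function(params) {
  m <- diabetes_marginal_effect(params)
  prev <- params$diabetes_prevalence
  if (is.null(params$diab_loghr)) {
    target <- params$mediated_fraction * params$causal_loghr_per_unit
    x <- target / m                       # required effective multiplier
    if (prev * x >= 1)
      stop("mediated_fraction unattainable: strengthen the BMI-diabetes ",
           "liability loading or lower the mediated fraction", call. = FALSE)
    beta_diab <- log1p(x / (1 - prev * x))
    beta_direct <- (1 - params$mediated_fraction) *
      params$causal_loghr_per_unit
  } else {
    beta_diab <- params$diab_loghr
    eff <- m * expm1(beta_diab) / (1 + prev * expm1(beta_diab))
    beta_direct <- params$causal_loghr_per_unit - eff
  }
  list(beta_direct = beta_direct, beta_diab = beta_diab,
       marginal_bmi_diab = m)
}

#' Simulate left-truncated, cause-labelled survival records
#'
#' Event times follow a Gompertz-baseline proportional-hazards model on the
#' attained-age timescale: log-hazard is linear in latent lifelong BMI
#' (direct effect), any-diabetes status (mediated pathway), the latent
#' confounder, and sex, with optional quadratic BMI curvature for J-shaped
#' scenarios. Individuals enter at their recruitment age and are censored
#' administratively at entry + follow-up or at the censoring age. Deaths
#' draw a leaf cause from the cause mix, with the renal and acute-diabetic-
#' crisis weights up-weighted for diabetic decedents.
#'
#' @param cohort output of \code{\link{simulate_phenotypes}}.
#' @param params a \code{\link{sim_params}} object.
#' @return data.frame with \code{individual_id}, \code{entry_age},
#'   \code{exit_age}, \code{died}, \code{cause} (leaf label or \code{"none"}).
#' @export
simulate_survival <- function(cohort, params) {
  validate_sim_params(params)
  set.seed(substream_seed(params$seed, "survival"))
  n <- nrow(cohort)
  co <- hazard_coefficients(params)
  bmi_ref <- sum(params$mean_bmi_by_sex * c(params$prop_male,
                                            1 - params$prop_male))
  bmi_c <- cohort$bmi_true - bmi_ref
  lp <- co$beta_direct * bmi_c +
    params$bmi_quadratic * bmi_c^2 +
    co$beta_diab * (cohort$diabetes != "none") +
    params$confounder_loghr * cohort$confounder +
    params$sex_loghr[as.character(cohort$sex)]
  if (any(!is.finite(lp)))
    stop("generation abort: non-finite linear predictor", call. = FALSE)

  theta <- params$gompertz_shape
  lambda <- params$gompertz_rate_ref
  if (is.null(lambda)) lambda <- gompertz_reference_rate(theta)

  # inverse-transform sampling of the conditional Gompertz event time
  u <- stats::runif(n)
  a <- cohort$entry_age
  tdeath <- 35 + log(exp(theta * (a - 35)) +
                       theta * (-log(u)) / (lambda * exp(lp))) / theta
  cens <- pmin(a + params$followup_years, params$admin_censor_age)
  died <- tdeath <= cens
  exit_age <- pmin(tdeath, cens)

  cause <- rep("none", n)
  if (any(died)) {
    mix <- params$cause_mix[cause_leaves()]
    w <- matrix(mix, sum(died), length(mix), byrow = TRUE)
    colnames(w) <- names(mix)
    dd <- cohort$diabetes[died] != "none"
    w[dd, "renal"] <- w[dd, "renal"] * params$diab_cause_multiplier
    w[dd, "acute_diabetic_crisis"] <-
      w[dd, "acute_diabetic_crisis"] * params$diab_cause_multiplier
    w <- w / rowSums(w)
    cw <- t(apply(w, 1, cumsum))
    cause[died] <- colnames(w)[max.col(cw >= stats::runif(sum(died)),
                                       ties.method = "first")]
  }
  data.frame(individual_id = cohort$individual_id,
             entry_age = a, exit_age = exit_age,
             died = died, cause = cause, stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running panel, genotype, phenotype, survival and
#' exclusion-flag generation under one seed. Identical parameters (including
#' the seed) replay byte-identically.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return list with \code{panel}, \code{dosages}, \code{cohort} (phenotypes
#'   joined with the survival record), \code{flags} (exclusion flags),
#'   \code{truth} (the hazard coefficients implied by the parameters) and
#'   \code{params}.
#' @export
simulate_cohort <- function(params) {
  panel <- simulate_panel(params)
  geno <- simulate_genotypes(panel, params)
  pheno <- simulate_phenotypes(geno, panel, params)
  surv <- simulate_survival(pheno, params)
  cohort <- cbind(pheno, surv[, c("exit_age", "died", "cause")])

  set.seed(substream_seed(params$seed, "flags"))
  n <- params$n_individuals
  flags <- data.frame(
    individual_id = cohort$individual_id,
    qc_fail = stats::runif(n) < params$exclusion_rates[["qc_fail"]],
    age_ge_90 = cohort$entry_age >= 90,
    implausible_anthropometry =
      stats::runif(n) < params$exclusion_rates[["implausible_anthropometry"]],
    uncertain_linkage =
      stats::runif(n) < params$exclusion_rates[["uncertain_linkage"]],
    stringsAsFactors = FALSE
  )
  list(panel = panel, dosages = geno$dosages, cohort = cohort,
       flags = flags, truth = hazard_coefficients(params), params = params)
}

#' Apply the sequential exclusion cascade
#'
#' Exclusions are applied in a fixed order (genetic QC, then age >= 90 at
#' recruitment, then implausible anthropometry, then uncertain mortality
#' linkage); each step's count is conditional on surviving the previous
#' steps, so an individual failing several criteria is counted once, at the
#' first. The remainder is split into the main analysis set (entry age
#' 35-74) and the older set (75-89).
#'
#' @param cohort cohort data.frame with \code{individual_id} and
#'   \code{entry_age}.
#' @param flags data.frame with logical columns \code{qc_fail},
#'   \code{age_ge_90}, \code{implausible_anthropometry},
#'   \code{uncertain_linkage} aligned with the cohort rows.
#' @return list: \code{analysis} (rows with entry age in [35, 75)),
#'   \code{older} (entry age in [75, 90)), and \code{ledger} (step, number
#'   remaining before the step, number removed, percentage of the initial
#'   cohort removed, rounded to 1 decimal).
#' @export
apply_exclusions <- function(cohort, flags) {
  steps <- c("qc_fail", "age_ge_90", "implausible_anthropometry",
             "uncertain_linkage")
  if (!all(steps %in% names(flags)))
    stop("flags must contain columns: ", paste(steps, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(setdiff(names(flags), "individual_id"), steps)
  if (length(extra))
    stop("unknown exclusion flag: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (nrow(flags) != nrow(cohort))
    stop("flags and cohort must align row-wise", call. = FALSE)

  n0 <- nrow(cohort)
  alive <- rep(TRUE, n0)
  ledger <- data.frame(step = steps, n_before = NA_integer_,
                       n_removed = NA_integer_, pct_of_initial = NA_real_)
  for (i in seq_along(steps)) {
    hit <- alive & flags[[steps[i]]]
    ledger$n_before[i] <- sum(alive)
    ledger$n_removed[i] <- sum(hit)
    ledger$pct_of_initial[i] <- round(100 * sum(hit) / n0, 1)
    alive <- alive & !hit
  }
  kept <- cohort[alive, , drop = FALSE]
  list(analysis = kept[kept$entry_age >= 35 & kept$entry_age < 75, ,
                       drop = FALSE],
       older = kept[kept$entry_age >= 75 & kept$entry_age < 90, ,
                    drop = FALSE],
       ledger = ledger)
}
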