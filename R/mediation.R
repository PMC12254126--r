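#' Proportion mediated from total and direct log hazard ratios
#'
#' \code{(loghr_total - loghr_direct) / loghr_total}: the fraction of the
#' exposure's log-HR effect routed through the mediator. Undefined (NA) when
#' the total log HR is below the floor in magnitude, which prevents ratio
#' blow-up in null resamples.
#'
#' @param loghr_total,loghr_direct log hazard ratios per exposure unit.
#' @param floor minimum \code{|loghr_total|} for the ratio to be defined.
#' @return numeric proportion (possibly NA).
#' @export
proportion_mediated <- function(loghr_total, loghr_direct, floor = 0.01) {
  if (!is.finite(loghr_total) || abs(loghr_total) < floor) return(NA_real_)
  (loghr_total - loghr_direct) / loghr_total
}

# Fast column-wise row subset (avoids rowname deduplication on resamples).
subset_rows <- function(df, idx) {
  structure(lapply(df, `[`, idx), class = "data.frame",
            row.names = c(NA_integer_, -length(idx)), names = names(df))
}

# One pass of the two-score mediation machinery on a row subset. Stage-1
# fits use the C-level QR (.lm.fit) on prebuilt design matrices: the
# bootstrap recomputes this whole function per resample, so the linear
# algebra stays lean. Total effect: 2SLS with the BMI score alone.
# Direct effect: textbook 2SLS with two endogenous regressors -- each of
# BMI and diabetes liability is regressed on BOTH scores, and the fitted
# values enter the Cox model jointly.
mediation_point <- function(idx, bmi_score, diab_score, exposure, mediator,
                            records, covariates, cause, window, floor) {
  bs <- bmi_score[idx]; ds <- diab_score[idx]
  y <- exposure[idx]; md <- as.numeric(mediator[idx])
  cv <- if (is.null(covariates)) NULL else subset_rows(covariates, idx)
  cvm <- if (is.null(cv)) NULL else as.matrix(cv)
  rec <- subset_rows(records, idx)

  x_tot <- cbind(1, score_bmi = bs, cvm)
  xhat_tot <- y - .lm.fit(x_tot, y)$residuals
  s2_tot <- fit_cox(rec, data.frame(xhat = xhat_tot), covariates = cv,
                    cause = cause, window = window, label = "total")

  x_j <- cbind(1, score_bmi = bs, score_diab = ds, cvm)
  qx <- qr(x_j)
  xhat <- data.frame(bmi_hat = qr.fitted(qx, y),
                     diab_hat = qr.fitted(qx, md))
  s2 <- fit_cox(rec, xhat, covariates = cv, cause = cause, window = window,
                label = "mediation")
  loghr_total <- s2_tot$beta_zy
  loghr_direct <- unname(s2$coef["bmi_hat"])
  list(loghr_total = loghr_total,
       loghr_direct = loghr_direct,
       se_total = s2_tot$se_zy,
       se_direct = unname(s2$se[match("bmi_hat", names(s2$coef))]),
       loghr_mediator = unname(s2$coef["diab_hat"]),
       proportion = proportion_mediated(loghr_total, loghr_direct, floor))
}

#' Two-score mediation MR: direct effect and proportion mediated
#'
#' Estimates the total causal effect of the exposure by 2SLS with the
#' exposure score alone, and the direct effect (not mediated by diabetes)
#' from a joint Cox model on genetically predicted exposure and genetically
#' predicted diabetes liability. Both first stages regress the endogenous
#' variable on both scores (standard 2SLS with two endogenous regressors):
#' the exposure score contributes to predicted diabetes liability through
#' its effect on the mediator, which is exactly the pathway the joint model
#' must hold fixed. The mediator first stage is a linear-probability fit on
#' diabetes status by default (keeps the 2SLS algebra exact); a probit
#' alternative is available.
#'
#' @param bmi_score,diab_score standardized scores built from disjoint
#'   variant panels (overlap is a hard error).
#' @param exposure exposure vector (measured BMI).
#' @param diabetes factor or logical mediator status (any diabetes).
#' @param records survival records aligned with the scores.
#' @param covariates optional adjustment covariates.
#' @param cause,window as in \code{\link{fit_cox}}.
#' @param floor minimum \code{|loghr_total|} for the proportion.
#' @param mediator_stage1 \code{"linear"} (default) or \code{"probit"}; the
#'   probit option replaces the mediator's fitted probabilities with the
#'   probit-model fitted values before the joint Cox fit.
#' @param bmi_variants,diab_variants optional character vectors of the
#'   variant ids behind each score, checked for disjointness.
#' @return list of class \code{"mediation_result"}: cause, total/direct log
#'   HRs (per exposure unit) with SEs, the mediator coefficient, and the
#'   proportion mediated.
#' @export
mediation_mr <- function(bmi_score, diab_score, exposure, diabetes, records,
                         covariates = NULL, cause = "all",
                         window = c(35, 75), floor = 0.01,
                         mediator_stage1 = c("linear", "probit"),
                         bmi_variants = NULL, diab_variants = NULL) {
  mediator_stage1 <- match.arg(mediator_stage1)
  if (!is.null(bmi_variants) && !is.null(diab_variants) &&
      length(intersect(bmi_variants, diab_variants)) > 0)
    stop("the two scores must be built from disjoint variant sets",
         call. = FALSE)
  med <- if (is.factor(diabetes)) diabetes != "none" else as.logical(diabetes)
  if (mediator_stage1 == "probit") {
    x1 <- data.frame(score_bmi = bmi_score, score_diab = diab_score)
    if (!is.null(covariates)) x1 <- cbind(x1, covariates)
    pr <- stats::glm(med ~ ., data = x1,
                     family = stats::binomial(link = "probit"))
    med <- stats::fitted(pr)
  }
  pt <- mediation_point(seq_along(bmi_score), bmi_score, diab_score,
                        exposure, med, records, covariates, cause, window,
                        floor)
  structure(c(list(cause = cause), pt), class = "mediation_result")
}

#' Bias-corrected bootstrap interval for the proportion mediated
#'
#' Resamples individuals with replacement, recomputes the full two-stage
#' mediation procedure per resample, and forms the bias-corrected (BC)
#' percentile interval: with \code{z0 = qnorm(} fraction of bootstrap
#' estimates below the point estimate \code{)}, the bounds sit at the
#' \code{pnorm(2 z0 -/+ 1.96)} percentiles of the bootstrap distribution.
#' Resamples whose total effect falls below the floor (proportion undefined)
#' or whose refit fails are dropped and counted.
#'
#' @inheritParams mediation_mr
#' @param n_boot number of resamples (the reference analysis used 1000).
#' @param seed integer seed for the resampling stream.
#' @param max_fail_frac flag the interval unreliable above this failed-
#'   resample fraction.
#' @return list: \code{ci_lo}, \code{ci_hi}, \code{n_boot_used},
#'   \code{n_failed}, \code{z0}, \code{reliable}, \code{boot} (the retained
#'   bootstrap proportions).
#' @export
bootstrap_proportion <- function(bmi_score, diab_score, exposure, diabetes,
                                 records, covariates = NULL, cause = "all",
                                 window = c(35, 75), floor = 0.01,
                                 n_boot = 1000, seed = 1L,
                                 max_fail_frac = 0.2) {
  med <- if (is.factor(diabetes)) diabetes != "none" else as.logical(diabetes)
  if (!is.null(window)) {
    # windowing commutes with resampling individuals, so do it once up front
    rec <- records
    rec$.row <- seq_len(nrow(rec))
    rec <- restrict_window(rec, window[1], window[2])
    rows <- rec$.row
    records <- rec[, setdiff(names(rec), ".row"), drop = FALSE]
    bmi_score <- bmi_score[rows]; diab_score <- diab_score[rows]
    exposure <- exposure[rows]; med <- med[rows]
    if (!is.null(covariates)) covariates <- covariates[rows, , drop = FALSE]
    window <- NULL
  }
  point <- mediation_point(seq_along(bmi_score), bmi_score, diab_score,
                           exposure, med, records, covariates, cause,
                           window, floor)
  if (!is.finite(point$proportion))
    stop("point estimate undefined; cannot bootstrap", call. = FALSE)
  n <- length(bmi_score)
  set.seed(substream_seed(seed, "mediation_bootstrap"))
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- try(mediation_point(idx, bmi_score, diab_score, exposure, med,
                               records, covariates, cause, window, floor),
               silent = TRUE)
    if (!inherits(res, "try-error")) vals[b] <- res$proportion
  }
  keep <- vals[is.finite(vals)]
  n_failed <- n_boot - length(keep)
  if (length(keep) < 2) stop("bootstrap produced too few usable resamples",
                             call. = FALSE)
  bc <- bc_interval(keep, point$proportion)
  list(ci_lo = bc$lo, ci_hi = bc$hi,
       n_boot_used = length(keep), n_failed = n_failed, z0 = bc$z0,
       point = point$proportion,
       reliable = n_failed <= max_fail_frac * n_boot,
       boot = keep)
}

# Bias-corrected percentile interval: percentiles pnorm(2 z0 +/- 1.96) of
# the bootstrap distribution, z0 = qnorm(fraction of draws below the point
# estimate), guarded at the extremes so the probit stays finite.
bc_interval <- function(boot, point, conf = 0.95) {
  if (length(unique(boot)) == 1)
    return(list(lo = boot[1], hi = boot[1], z0 = 0))
  prop_below <- mean(boot < point)
  prop_below <- min(max(prop_below, 0.5 / length(boot)),
                    1 - 0.5 / length(boot))
  z0 <- stats::qnorm(prop_below)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- unname(stats::quantile(boot,
                               c(stats::pnorm(2 * z0 - zc),
                                 stats::pnorm(2 * z0 + zc)), type = 7))
  list(lo = ci[1], hi = ci[2], z0 = z0)
}
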