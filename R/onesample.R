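#' Construct a causal estimate (log HR per exposure unit)
#'
#' @param beta_iv log hazard ratio per 1 kg/m2 of exposure.
#' @param se_iv its standard error.
#' @param label estimate label (cause x subset).
#' @param report_scale reporting scale in kg/m2 (default 5); the hazard
#'   ratio and 95% CI are \code{exp(report_scale * (beta_iv +/- 1.96 se))}.
#' @param flags character vector of quality flags (e.g. weak instrument).
#' @return list of class \code{"causal_estimate"}.
#' @export
causal_estimate <- function(beta_iv, se_iv, label = "", report_scale = 5,
                            flags = character(0)) {
  z <- stats::qnorm(0.975)
  structure(list(label = label, beta_iv = beta_iv, se_iv = se_iv,
                 report_scale = report_scale,
                 hr_scaled = exp(report_scale * beta_iv),
                 ci_lo = exp(report_scale * (beta_iv - z * se_iv)),
                 ci_hi = exp(report_scale * (beta_iv + z * se_iv)),
                 flags = flags),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("%s: HR per %g kg/m2 = %.2f (95%% CI %.2f-%.2f)%s\n",
              if (nzchar(x$label)) x$label else "causal estimate",
              x$report_scale, x$hr_scaled, x$ci_lo, x$ci_hi,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' One-sample Wald ratio with a delta-method standard error
#'
#' Divides the instrument-outcome log hazard ratio by the instrument-exposure
#' slope (both per SD of the score), giving a log HR per exposure unit. The
#' SE uses the two-term delta method:
#' \code{sqrt(se_zy^2/beta_zx^2 + beta_zy^2 se_zx^2 / beta_zx^4)}.
#' A first-stage F below the weak-instrument floor flags (never suppresses)
#' the estimate.
#'
#' @param zy an outcome fit from \code{\link{fit_cox}} (or a list with
#'   \code{beta_zy}, \code{se_zy}).
#' @param zx an instrument fit from \code{\link{instrument_strength}} (or a
#'   list with \code{beta_zx}, \code{se_zx}, \code{f_statistic}).
#' @param report_scale reporting scale in exposure units (default 5 kg/m2).
#' @param f_floor weak-instrument flag threshold (default 10).
#' @param label estimate label; defaults to cause x subset of the inputs.
#' @return A \code{\link{causal_estimate}}.
#' @export
wald_ratio <- function(zy, zx, report_scale = 5, f_floor = 10,
                       label = NULL) {
  if (zx$beta_zx == 0) stop("zero first-stage slope", call. = FALSE)
  beta <- zy$beta_zy / zx$beta_zx
  se <- sqrt(zy$se_zy^2 / zx$beta_zx^2 +
               zy$beta_zy^2 * zx$se_zx^2 / zx$beta_zx^4)
  flags <- character(0)
  if (!is.null(zx$f_statistic) && is.finite(zx$f_statistic) &&
      zx$f_statistic < f_floor)
    flags <- "weak_instrument"
  if (is.null(label))
    label <- paste0(if (!is.null(zy$cause)) zy$cause else "outcome", ":",
                    if (!is.null(zy$label)) zy$label else "all")
  causal_estimate(beta, se, label = label, report_scale = report_scale,
                  flags = flags)
}

#' Inverse-variance-weighted pooling of causal estimates
#'
#' Fixed-effect precision weighting on the log-HR scale:
#' \code{beta = sum(w b) / sum(w)} with \code{w = 1/se^2} and
#' \code{se = 1/sqrt(sum(w))}. All inputs must share a report scale.
#'
#' @param estimates list of \code{\link{causal_estimate}} objects.
#' @param label label for the pooled estimate.
#' @return A \code{\link{causal_estimate}}.
#' @export
ivw_pool <- function(estimates, label = "pooled") {
  stopifnot(length(estimates) >= 1)
  scales <- vapply(estimates, `[[`, numeric(1), "report_scale")
  if (length(unique(scales)) > 1)
    stop("cannot pool estimates on different report scales", call. = FALSE)
  b <- vapply(estimates, `[[`, numeric(1), "beta_iv")
  s <- vapply(estimates, `[[`, numeric(1), "se_iv")
  w <- 1 / s^2
  causal_estimate(sum(w * b) / sum(w), 1 / sqrt(sum(w)), label = label,
                  report_scale = scales[1],
                  flags = unique(unlist(lapply(estimates, `[[`, "flags"))))
}

#' Two-stage least squares with a proportional-hazards second stage
#'
#' Stage 1 regresses the exposure on the score(s) plus covariates; stage 2
#' fits the windowed cause-specific Cox model on the stage-1 fitted values
#' (plus the same covariates). The coefficient on predicted exposure is the
#' causal log HR per exposure unit; its SE is the second-stage model SE,
#' uncorrected for first-stage uncertainty (the Wald-ratio delta SE is the
#' primary inferential path; the mediation bootstrap covers the joint
#' uncertainty where it matters).
#'
#' @param scores vector or data.frame of instrument scores.
#' @param exposure exposure vector.
#' @param records survival records aligned with the scores.
#' @param covariates optional adjustment covariates (enter both stages).
#' @param cause,window,label as in \code{\link{fit_cox}}.
#' @param report_scale reporting scale (default 5 kg/m2).
#' @return A \code{\link{causal_estimate}} with the stage fits attached as
#'   attributes \code{"stage1"} and \code{"stage2"}.
#' @export
tsls_estimate <- function(scores, exposure, records, covariates = NULL,
                          cause = "all", window = c(35, 75), label = NULL,
                          report_scale = 5) {
  scores <- as.data.frame(scores)
  x1 <- if (is.null(covariates)) scores else cbind(scores, covariates)
  s1 <- fit_linear(exposure, x1)
  xhat <- data.frame(xhat = s1$fitted)
  s2 <- fit_cox(records, xhat, covariates = covariates, cause = cause,
                window = window,
                label = if (is.null(label)) cause else label)
  est <- causal_estimate(s2$beta_zy, s2$se_zy,
                         label = if (is.null(label)) paste0(cause, ":2sls")
                                 else label,
                         report_scale = report_scale)
  attr(est, "stage1") <- s1
  attr(est, "stage2") <- s2
  est
}

#' Cochran Q heterogeneity statistic
#'
#' @param betas,ses estimate vectors.
#' @return list: \code{Q}, \code{df}, \code{p}.
#' @export
cochran_q <- function(betas, ses) {
  w <- 1 / ses^2
  mu <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - mu)^2)
  df <- length(betas) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

# Inverse-variance-weighted linear trend of estimates on level midpoints.
ivw_trend <- function(betas, ses, x) {
  w <- 1 / ses^2
  xw <- sum(w * x) / sum(w)
  sxx <- sum(w * (x - xw)^2)
  slope <- sum(w * (x - xw) * betas) / sxx
  se <- 1 / sqrt(sxx)
  z <- slope / se
  list(slope = slope, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Subgroup Wald-ratio analysis with heterogeneity and trend tests
#'
#' Estimates the causal log HR separately within the levels of a subgrouping
#' dimension, using either the global first-stage denominator or a
#' level-specific one, and reports across-level Cochran Q plus (for ordered
#' dimensions) an inverse-variance-weighted linear trend over level
#' midpoints. Age bands are implemented by window restriction on the
#' attained-age timescale; other dimensions subset individuals.
#'
#' @param dimension one of \code{"age_band"}, \code{"ancestry_tertile"},
#'   \code{"district"}, \code{"smoking"}, \code{"activity"}.
#' @param cohort cohort data.frame (phenotypes + survival columns).
#' @param std_score standardized instrument score aligned with the cohort.
#' @param exposure exposure vector aligned with the cohort.
#' @param covariates optional adjustment covariates.
#' @param cause target cause.
#' @param denominator \code{"global"} or \code{"subgroup"} first stage.
#' @param age_bands list of [lo, hi) windows used when
#'   \code{dimension = "age_band"}.
#' @param report_scale reporting scale.
#' @param min_events per-level event floor; sparser levels are dropped with
#'   a warning.
#' @return list: \code{estimates} (named list of \code{causal_estimate}),
#'   \code{heterogeneity} (Cochran Q), \code{trend} (NULL for unordered
#'   dimensions), \code{midpoints}.
#' @export
subgroup_analysis <- function(dimension = c("age_band", "ancestry_tertile",
                                            "district", "smoking",
                                            "activity"),
                              cohort, std_score, exposure,
                              covariates = NULL, cause = "all",
                              denominator = c("global", "subgroup"),
                              age_bands = list(c(35, 60), c(60, 70),
                                               c(70, 75)),
                              report_scale = 5, min_events = 10) {
  dimension <- match.arg(dimension)
  denominator <- match.arg(denominator)
  zx_global <- instrument_strength(std_score, exposure,
                                   covariates = covariates, label = "global")
  records <- cohort[, c("entry_age", "exit_age", "died", "cause")]

  ests <- list(); mids <- numeric(0)
  if (dimension == "age_band") {
    for (w in age_bands) {
      lab <- sprintf("%d-%d", w[1], w[2] - 1)
      zy <- try(fit_cox(records, std_score, covariates = covariates,
                        cause = cause, window = w, label = lab,
                        min_events = min_events), silent = TRUE)
      if (inherits(zy, "try-error")) {
        warning("dropping sparse age band ", lab, call. = FALSE)
        next
      }
      ests[[lab]] <- wald_ratio(zy, zx_global, report_scale = report_scale,
                                label = lab)
      mids <- c(mids, mean(w))
    }
    ordered <- TRUE
  } else {
    grp <- switch(dimension,
      ancestry_tertile = cut(cohort$ancestry_prop,
                             stats::quantile(cohort$ancestry_prop,
                                             c(0, 1/3, 2/3, 1)),
                             include.lowest = TRUE,
                             labels = c("low", "mid", "high")),
      district = cohort$district,
      smoking = cohort$smoking,
      activity = cohort$activity)
    ordered <- dimension == "ancestry_tertile"
    for (lv in levels(grp)) {
      i <- which(grp == lv)
      if (length(i) == 0) { warning("empty level ", lv, call. = FALSE); next }
      zx <- if (denominator == "global") zx_global else
        instrument_strength(std_score[i], exposure[i],
                            covariates = if (is.null(covariates)) NULL else
                              covariates[i, , drop = FALSE],
                            label = lv)
      zy <- try(fit_cox(records[i, , drop = FALSE], std_score[i],
                        covariates = if (is.null(covariates)) NULL else
                          covariates[i, , drop = FALSE],
                        cause = cause, label = lv,
                        min_events = min_events), silent = TRUE)
      if (inherits(zy, "try-error")) {
        warning("dropping sparse level ", lv, call. = FALSE)
        next
      }
      ests[[lv]] <- wald_ratio(zy, zx, report_scale = report_scale,
                               label = lv)
      mids <- c(mids, match(lv, levels(grp)))
    }
  }
  if (length(ests) == 0) stop("no estimable subgroup level", call. = FALSE)
  b <- vapply(ests, `[[`, numeric(1), "beta_iv")
  s <- vapply(ests, `[[`, numeric(1), "se_iv")
  list(estimates = ests,
       heterogeneity = cochran_q(b, s),
       trend = if (ordered && length(ests) >= 2) ivw_trend(b, s, mids)
               else NULL,
       midpoints = mids)
}
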