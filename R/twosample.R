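#' Per-variant association summaries for summary-statistic MR
#'
#' Runs one marginal linear exposure regression and one marginal
#' cause-specific Cox outcome regression per variant (each adjusted for the
#' covariates), then harmonizes every variant to its exposure-increasing
#' allele so that \code{beta_zx >= 0}, flipping the outcome beta in tandem.
#' Monomorphic variants are dropped with a warning.
#'
#' @param dosages individuals x variants dosage matrix.
#' @param exposure exposure vector.
#' @param records survival records aligned with the dosage rows.
#' @param covariates optional adjustment covariates.
#' @param cause,window as in \code{\link{fit_cox}}.
#' @return data.frame of class \code{"snp_summary"}: \code{variant_id},
#'   \code{beta_zx}, \code{se_zx}, \code{beta_zy}, \code{se_zy}.
#' @export
per_snp_summaries <- function(dosages, exposure, records, covariates = NULL,
                              cause = "all", window = c(35, 75)) {
  if (ncol(dosages) < 3) stop("need at least 3 variants", call. = FALSE)
  rows <- list()
  for (j in seq_len(ncol(dosages))) {
    d <- dosages[, j]
    if (stats::sd(d) == 0) {
      warning("dropping monomorphic variant ", colnames(dosages)[j],
              call. = FALSE)
      next
    }
    x1 <- data.frame(dose = d)
    if (!is.null(covariates)) x1 <- cbind(x1, covariates)
    fx <- fit_linear(exposure, x1)
    fy <- fit_cox(records, data.frame(dose = d), covariates = covariates,
                  cause = cause, window = window, min_events = 1)
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = colnames(dosages)[j],
      beta_zx = unname(fx$coef["dose"]), se_zx = unname(fx$se["dose"]),
      beta_zy = fy$beta_zy, se_zy = fy$se_zy, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  harmonize_summaries(out)
}

#' Harmonize summary statistics to the exposure-increasing allele
#'
#' @param summ data.frame with \code{beta_zx}, \code{beta_zy} (SEs pass
#'   through unchanged).
#' @return The same data.frame with \code{beta_zx >= 0} everywhere.
#' @export
harmonize_summaries <- function(summ) {
  flip <- summ$beta_zx < 0
  summ$beta_zx[flip] <- -summ$beta_zx[flip]
  summ$beta_zy[flip] <- -summ$beta_zy[flip]
  class(summ) <- c("snp_summary", "data.frame")
  summ
}

#' Two-sample inverse-variance-weighted estimator
#'
#' Weighted regression of the outcome betas on the exposure betas through
#' the origin with weights \code{1/se_zy^2}. When Cochran Q exceeds its
#' degrees of freedom, the SE is inflated multiplicatively by
#' \code{sqrt(Q/df)} (multiplicative random effects); both variants are
#' recorded in the flags.
#'
#' @param summ a harmonized \code{snp_summary} data.frame.
#' @param report_scale reporting scale.
#' @return A \code{\link{causal_estimate}} with attributes \code{"Q"} and
#'   \code{"Q_df"}.
#' @export
ivw_2s <- function(summ, report_scale = 5) {
  stopifnot(nrow(summ) >= 2)
  w <- 1 / summ$se_zy^2
  beta <- sum(w * summ$beta_zx * summ$beta_zy) / sum(w * summ$beta_zx^2)
  se_fixed <- 1 / sqrt(sum(w * summ$beta_zx^2))
  Q <- sum(w * (summ$beta_zy - beta * summ$beta_zx)^2)
  df <- nrow(summ) - 1L
  infl <- if (Q > df) sqrt(Q / df) else 1
  est <- causal_estimate(beta, se_fixed * infl, label = "ivw_2s",
                         report_scale = report_scale,
                         flags = if (infl > 1) "random_effects" else
                           "fixed_effect")
  attr(est, "Q") <- Q
  attr(est, "Q_df") <- df
  est
}

# Weighted median of per-variant ratios: order the ratios, centre each
# variant's normalized weight at its cumulative midpoint, and linearly
# interpolate the ratio where the midpoints cross 50%.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  mid <- cumsum(w) - w / 2
  if (mid[1] >= 0.5) return(r[1])
  if (mid[length(mid)] <= 0.5) return(r[length(r)])
  stats::approx(mid, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Per-variant Wald ratios \code{beta_zy/beta_zx} are ordered and the
#' estimate is the ratio at 50% of cumulative normalized inverse-variance
#' weight (first-order delta ratio SE \code{se_zy/beta_zx}), linearly
#' interpolated. The SE comes from a seeded parametric bootstrap of the
#' summary statistics. Consistent when at least half the weight comes from
#' valid instruments.
#'
#' @param summ harmonized \code{snp_summary} data.frame (>= 3 variants).
#' @param n_boot parametric bootstrap draws for the SE.
#' @param seed seed for the bootstrap stream.
#' @param report_scale reporting scale.
#' @return A \code{\link{causal_estimate}}.
#' @export
weighted_median <- function(summ, n_boot = 1000, seed = 1L,
                            report_scale = 5) {
  stopifnot(nrow(summ) >= 3)
  ratio <- summ$beta_zy / summ$beta_zx
  w <- (summ$beta_zx / summ$se_zy)^2  # 1 / var of the delta-method ratio
  est <- weighted_median_point(ratio, w)
  set.seed(substream_seed(seed, "weighted_median"))
  k <- nrow(summ)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, summ$beta_zx, summ$se_zx)
    by <- stats::rnorm(k, summ$beta_zy, summ$se_zy)
    weighted_median_point(by / bx, (bx / summ$se_zy)^2)
  }, numeric(1))
  causal_estimate(est, stats::sd(boots), label = "weighted_median",
                  report_scale = report_scale)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with a
#' free intercept (weights \code{1/se_zy^2}): the slope estimates the causal
#' effect under the InSIDE assumption and the intercept tests directional
#' pleiotropy. SEs use multiplicative random effects with the residual
#' dispersion floored at 1 (no shrinking below the fixed-effect SE). The
#' I-squared(GX) statistic quantifies regression-dilution weakness of the
#' exposure betas.
#'
#' @param summ harmonized \code{snp_summary} data.frame (>= 3 variants).
#' @param report_scale reporting scale.
#' @return list of class \code{"mr_egger"}: \code{slope} (a
#'   \code{\link{causal_estimate}}), \code{intercept}, \code{intercept_se},
#'   \code{intercept_p}, \code{i2_gx}.
#' @export
mr_egger <- function(summ, report_scale = 5) {
  stopifnot(nrow(summ) >= 3)
  if (stats::sd(summ$beta_zx) < 1e-12 ||
      stats::var(summ$beta_zx) / mean(summ$beta_zx^2) < 1e-6)
    stop("no spread in the exposure betas; Egger regression undefined",
         call. = FALSE)
  w <- 1 / summ$se_zy^2
  fit <- stats::lm(beta_zy ~ beta_zx, data = summ, weights = w)
  sm <- summary(fit)
  disp <- max(1, sm$sigma)  # multiplicative random effects, floored
  co <- sm$coefficients
  slope_se <- co["beta_zx", "Std. Error"] / sm$sigma * disp
  int_se <- co["(Intercept)", "Std. Error"] / sm$sigma * disp
  zi <- co["(Intercept)", "Estimate"] / int_se
  wx <- 1 / summ$se_zx^2
  bx_bar <- sum(wx * summ$beta_zx) / sum(wx)
  q_gx <- sum(wx * (summ$beta_zx - bx_bar)^2)
  structure(list(
    slope = causal_estimate(co["beta_zx", "Estimate"], slope_se,
                            label = "mr_egger", report_scale = report_scale),
    intercept = co["(Intercept)", "Estimate"],
    intercept_se = int_se,
    intercept_p = 2 * stats::pnorm(-abs(zi)),
    i2_gx = max(0, (q_gx - (nrow(summ) - 1)) / q_gx)),
    class = "mr_egger")
}
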