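#' Residual-method stratification for non-linear MR
#'
#' Subtracts the instrument-predicted component from the exposure (linear
#' fit on the score plus covariates) and partitions individuals into q
#' equal-size groups of the residual (stable tie-break by row order; sizes
#' differ by at most one).
#'
#' @param exposure exposure vector.
#' @param std_score standardized instrument score.
#' @param covariates optional covariates for the first stage.
#' @param q number of strata (>= 2).
#' @return integer stratum assignment in 1..q.
#' @export
residual_strata <- function(exposure, std_score, covariates = NULL, q = 10) {
  stopifnot(q >= 2)
  x <- data.frame(score = std_score)
  if (!is.null(covariates)) x <- cbind(x, covariates)
  res <- fit_linear(exposure, x)$residuals
  r <- rank(res, ties.method = "first")
  as.integer(floor((r - 1) * q / length(r)) + 1L)
}

#' Doubly ranked stratification for non-linear MR
#'
#' Individuals are ranked by the instrument and cut into consecutive
#' pre-strata of size q; within each pre-stratum they are re-ranked by
#' exposure, and the k-th ranked member of every pre-stratum joins stratum
#' k. A short remainder pre-stratum is mapped proportionally onto 1..q.
#' This construction keeps the instrument-exposure relationship coherent
#' within strata even under effect heterogeneity, where residual-method
#' strata can fail. Refuses (rather than degrades) when n < q^2, since the
#' pre-strata would not span the instrument range.
#'
#' @param exposure exposure vector.
#' @param std_score standardized instrument score.
#' @param q number of strata (>= 2); requires \code{length(exposure) >= q^2}.
#' @return integer stratum assignment in 1..q.
#' @export
doubly_ranked_strata <- function(exposure, std_score, q = 10) {
  stopifnot(q >= 2)
  n <- length(exposure)
  if (n < q^2) stop("doubly ranked stratification needs n >= q^2 (n = ", n,
                    ", q = ", q, ")", call. = FALSE)
  ord <- order(std_score, seq_len(n))  # stable
  pre <- floor((seq_len(n) - 1) / q) + 1L  # pre-stratum of each sorted pos
  stratum <- integer(n)
  for (b in unique(pre)) {
    idx <- ord[pre == b]
    r <- rank(exposure[idx], ties.method = "first")
    m <- length(idx)
    if (m == q) {
      stratum[idx] <- r
    } else {
      stratum[idx] <- as.integer(floor((r - 1) * q / m) + 1L)
    }
  }
  stratum
}

#' Per-stratum Wald ratios with heterogeneity and trend across strata
#'
#' Runs the full one-sample machinery within each stratum (stratum-specific
#' first-stage denominator), then summarises non-linearity by Cochran Q
#' across the stratum estimates and by an inverse-variance-weighted linear
#' trend of the stratum log HRs on the stratum mean exposures. A stratum
#' with fewer events than the floor is merged with its lower neighbour
#' (with a warning).
#'
#' @param stratum integer stratum assignment (1..q).
#' @param cohort cohort data.frame carrying the survival columns.
#' @param std_score,exposure aligned vectors.
#' @param covariates optional adjustment covariates.
#' @param cause,window as in \code{\link{fit_cox}}.
#' @param report_scale reporting scale.
#' @param min_events event floor per stratum.
#' @return list of class \code{"stratum_mr"}: \code{table} (stratum, n,
#'   mean exposure, beta, se, hr_scaled), \code{estimates},
#'   \code{heterogeneity}, \code{trend}.
#' @export
stratum_mr <- function(stratum, cohort, std_score, exposure,
                       covariates = NULL, cause = "all", window = c(35, 75),
                       report_scale = 5, min_events = 10) {
  records <- cohort[, c("entry_age", "exit_age", "died", "cause")]
  # merge event-sparse strata downward before estimating
  repeat {
    lv <- sort(unique(stratum))
    ev <- vapply(lv, function(k) {
      r <- restrict_window(records[stratum == k, , drop = FALSE],
                           window[1], window[2])
      sum(r$died & cause_matches(r$cause, cause))
    }, numeric(1))
    if (all(ev >= min_events) || length(lv) == 1) break
    k <- lv[which(ev < min_events)[1]]
    tgt <- if (k == lv[1]) lv[2] else lv[match(k, lv) - 1]
    warning("merging sparse stratum ", k, " into ", tgt, call. = FALSE)
    stratum[stratum == k] <- tgt
  }
  lv <- sort(unique(stratum))
  ests <- list(); mx <- numeric(0); ns <- integer(0)
  for (k in lv) {
    i <- which(stratum == k)
    zx <- instrument_strength(std_score[i], exposure[i],
                              covariates = if (is.null(covariates)) NULL
                                           else covariates[i, , drop = FALSE],
                              label = paste0("stratum", k))
    zy <- fit_cox(records[i, , drop = FALSE], std_score[i],
                  covariates = if (is.null(covariates)) NULL
                               else covariates[i, , drop = FALSE],
                  cause = cause, window = window,
                  label = paste0("stratum", k), min_events = min_events)
    ests[[as.character(k)]] <- wald_ratio(zy, zx,
                                          report_scale = report_scale,
                                          label = paste0("stratum", k))
    mx <- c(mx, mean(exposure[i]))
    ns <- c(ns, length(i))
  }
  b <- vapply(ests, `[[`, numeric(1), "beta_iv")
  s <- vapply(ests, `[[`, numeric(1), "se_iv")
  tab <- data.frame(stratum = lv, n = ns, mean_exposure = mx,
                    beta_iv = b, se_iv = s,
                    hr_scaled = exp(report_scale * b), row.names = NULL)
  structure(list(table = tab, estimates = ests,
                 heterogeneity = if (length(lv) > 1) cochran_q(b, s)
                                 else list(Q = 0, df = 0, p = NA_real_),
                 trend = if (length(lv) > 1) ivw_trend(b, s, mx) else NULL),
            class = "stratum_mr")
}

#' Negative-control diagnostics for stratified non-linear MR
#'
#' Within each stratum, regresses a variable the instrument cannot causally
#' affect (recruitment age, or sex on the log-odds scale) on the score. A
#' valid stratification yields null associations in every stratum; non-null
#' associations flag selection distortion introduced by the stratification
#' or the design. Emitted as a diagnostic table only, never auto-acted on.
#'
#' @param stratum integer stratum assignment.
#' @param std_score standardized instrument score.
#' @param control the control variable (numeric entry age, or a two-level
#'   sex factor).
#' @param type \code{"age"} (linear) or \code{"sex"} (logistic).
#' @return data.frame: stratum, estimate, se, z, p.
#' @export
negative_control <- function(stratum, std_score, control,
                             type = c("age", "sex")) {
  type <- match.arg(type)
  rows <- lapply(sort(unique(stratum)), function(k) {
    i <- which(stratum == k)
    if (type == "age") {
      f <- fit_linear(control[i], data.frame(score = std_score[i]))
      est <- unname(f$coef["score"]); se <- unname(f$se["score"])
    } else {
      y <- as.integer(control[i] == levels(factor(control))[2])
      f <- stats::glm(y ~ std_score[i], family = stats::binomial())
      est <- unname(stats::coef(f)[2])
      se <- unname(sqrt(diag(stats::vcov(f)))[2])
    }
    data.frame(stratum = k, estimate = est, se = se, z = est / se,
               p = 2 * stats::pnorm(-abs(est / se)))
  })
  do.call(rbind, rows)
}
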