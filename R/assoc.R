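#' Ordinary least squares with classical standard errors
#'
#' The linear engine behind every first-stage fit: OLS of an exposure on an
#' arbitrary regressor set, returning the full coefficient vector and
#' covariance. Rank-deficient design columns are dropped with a warning.
#'
#' @param y response vector.
#' @param x data.frame or matrix of regressors (an intercept is added).
#' @return list: \code{coef}, \code{se}, \code{vcov}, \code{fitted},
#'   \code{residuals}, \code{n}.
#' @export
fit_linear <- function(y, x) {
  x <- as.data.frame(x)
  if (nrow(x) != length(y)) stop("y and x must align", call. = FALSE)
  ok <- stats::complete.cases(y, x)
  if (all(vapply(x, is.numeric, logical(1)))) {
    mm <- cbind("(Intercept)" = 1, as.matrix(x[ok, , drop = FALSE]))
  } else {
    mm <- stats::model.matrix(~ ., data = x[ok, , drop = FALSE])
  }
  mm <- drop_aliased(mm)
  n <- nrow(mm)
  if (n <= ncol(mm)) stop("not enough observations for the regressors",
                          call. = FALSE)
  fit <- stats::lm.fit(mm, y[ok])
  sigma2 <- sum(fit$residuals^2) / (n - ncol(mm))
  vc <- sigma2 * chol2inv(chol(crossprod(mm)))
  dimnames(vc) <- list(colnames(mm), colnames(mm))
  list(coef = fit$coefficients, se = sqrt(diag(vc)), vcov = vc,
       fitted = fit$fitted.values, residuals = fit$residuals, n = n)
}

#' Restrict survival records to an age window
#'
#' Half-open window [lo, hi): entry is delayed to \code{max(entry, lo)};
#' records exiting at or before \code{lo} are dropped; events at or beyond
#' \code{hi} are recoded as censored at \code{hi}.
#'
#' @param records data.frame with \code{entry_age}, \code{exit_age},
#'   \code{died}, \code{cause} (other columns pass through).
#' @param age_lo,age_hi window bounds, \code{age_lo < age_hi}.
#' @return The windowed records (possibly fewer rows).
#' @export
restrict_window <- function(records, age_lo, age_hi) {
  stopifnot(age_lo < age_hi)
  r <- records[records$exit_age > age_lo, , drop = FALSE]
  r$entry_age <- pmax(r$entry_age, age_lo)
  over <- r$exit_age >= age_hi
  r$exit_age[over] <- age_hi
  r$died[over] <- FALSE
  if ("cause" %in% names(r)) r$cause[over] <- "none"
  r <- r[r$exit_age > r$entry_age, , drop = FALSE]
  r
}

#' Cause-specific Cox fit of mortality on a score
#'
#' The survival engine behind every second-stage fit: a proportional-hazards
#' partial-likelihood fit on the attained-age timescale with delayed entry
#' and Efron tie handling. The target cause's deaths are the events; deaths
#' from competing causes are censored at their death age; the age window is
#' applied first (see \code{\link{restrict_window}}).
#'
#' @param records survival records (\code{entry_age}, \code{exit_age},
#'   \code{died}, \code{cause}).
#' @param score the per-individual predictor (e.g. standardized score, or a
#'   matrix/data.frame of several predictors), aligned with \code{records}.
#' @param covariates optional data.frame of adjustment covariates
#'   (typically genotype principal components).
#' @param cause target cause label in the hierarchy (default \code{"all"}).
#' @param window age window, default c(35, 75); \code{NULL} for none.
#' @param label subset label carried into the result.
#' @param min_events refuse to fit below this event count.
#' @return list of class \code{"outcome_fit"}: \code{label}, \code{cause},
#'   \code{beta_zy}, \code{se_zy} (first predictor), \code{coef}, \code{se}
#'   (all predictors), \code{n_events}, \code{n_at_risk}, \code{converged}.
#' @export
fit_cox <- function(records, score, covariates = NULL, cause = "all",
                    window = c(35, 75), label = "all", min_events = 10) {
  score <- as.data.frame(score)
  if (ncol(score) == 1) names(score) <- "score"
  stopifnot(nrow(score) == nrow(records))
  dat <- cbind(records[, c("entry_age", "exit_age", "died", "cause")], score)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == nrow(records))
    dat <- cbind(dat, covariates)
  }
  if (!is.null(window)) dat <- restrict_window(dat, window[1], window[2])
  event <- dat$died & cause_matches(dat$cause, cause)
  n_events <- sum(event)
  if (n_events < 1) stop("no events of cause '", cause, "' in the window",
                         call. = FALSE)
  if (n_events < min_events)
    stop("too few events (", n_events, ") of cause '", cause, "'",
         call. = FALSE)
  pred <- dat[, setdiff(names(dat),
                        c("entry_age", "exit_age", "died", "cause")),
              drop = FALSE]
  if (all(vapply(pred, is.numeric, logical(1)))) {
    x <- as.matrix(pred)
  } else {
    x <- stats::model.matrix(~ ., data = pred)[, -1, drop = FALSE]
  }
  fit <- survival::agreg.fit(
    x, survival::Surv(dat$entry_age, dat$exit_age, event),
    strata = NULL, offset = NULL, init = NULL,
    control = survival::coxph.control(eps = 1e-11, iter.max = 30),
    weights = NULL, method = "efron", rownames = NULL)
  cf <- fit$coefficients
  names(cf) <- colnames(x)
  conv <- all(is.finite(cf)) && fit$iter < 30
  if (!conv) warning("Cox fit did not converge for cause '", cause,
                     "' (", label, ")", call. = FALSE)
  ses <- sqrt(diag(as.matrix(fit$var)))
  k <- match(names(score)[1], names(cf))
  structure(list(label = label, cause = cause,
                 beta_zy = unname(cf[k]),
                 se_zy = ses[k],
                 coef = cf,
                 se = ses,
                 n_events = n_events, n_at_risk = nrow(dat),
                 converged = conv),
            class = "outcome_fit")
}
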