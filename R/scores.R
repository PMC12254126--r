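#' Compute a weighted allele score from dosages
#'
#' Additive model: the raw score is the weight-by-dosage sum over the panel
#' variants of one trait. Dosages whose counted allele is the panel's other
#' allele are flipped (2 - dosage) with a warning; an unresolvable allele is
#' an error. Missing dosages are mean-imputed at twice the allele frequency
#' (the Hardy-Weinberg expectation) under the default policy, or cause the
#' individual's score to be NA under \code{missing_policy = "na"}. A variant
#' with more than \code{max_missing} missing dosages is a hard error.
#'
#' @param dosages numeric matrix, individuals x variants, columns named by
#'   variant id; the allele counted by each column may be supplied in
#'   \code{attr(dosages, "counted_allele")} (named character vector) and
#'   defaults to the panel's effect allele.
#' @param panel variant panel rows for one trait (see
#'   \code{\link{simulate_panel}} for the column contract).
#' @param missing_policy \code{"mean"} (impute 2p) or \code{"na"}.
#' @param max_missing maximum tolerated missingness fraction per variant.
#' @return data.frame with \code{individual_id} (rownames of \code{dosages}
#'   or a running index), \code{raw_score}, and \code{std_score}
#'   (standardized to mean 0, SD 1 over non-missing individuals).
#' @export
compute_score <- function(dosages, panel, missing_policy = c("mean", "na"),
                          max_missing = 0.10) {
  missing_policy <- match.arg(missing_policy)
  if (length(unique(panel$trait)) > 1)
    stop("panel must contain a single trait; subset it first", call. = FALSE)
  miss_col <- !(panel$variant_id %in% colnames(dosages))
  x <- matrix(NA_real_, nrow(dosages), nrow(panel),
              dimnames = list(NULL, panel$variant_id))
  x[, panel$variant_id[!miss_col]] <-
    dosages[, panel$variant_id[!miss_col], drop = FALSE]

  counted <- attr(dosages, "counted_allele")
  if (!is.null(counted)) {
    for (j in which(!miss_col)) {
      vid <- panel$variant_id[j]
      ca <- counted[[vid]]
      if (is.null(ca) || is.na(ca)) next
      if (ca == panel$effect_allele[j]) next
      if (ca == panel$other_allele[j]) {
        warning("flipping dosage orientation for ", vid, call. = FALSE)
        x[, vid] <- 2 - x[, vid]
      } else {
        stop("allele ", ca, " for ", vid,
             " matches neither effect nor other allele", call. = FALSE)
      }
    }
  }

  frac_miss <- colMeans(is.na(x))
  if (any(frac_miss > max_missing & frac_miss < 1))
    stop("variant(s) exceed ", 100 * max_missing, "% missing dosages: ",
         paste(colnames(x)[frac_miss > max_missing & frac_miss < 1],
               collapse = ", "), call. = FALSE)
  if (missing_policy == "mean") {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- 2 * panel$allele_freq[j]
    }
  }
  raw <- as.numeric(x %*% panel$weight)
  std <- raw
  ok <- !is.na(raw)
  if (sum(ok) > 1 && stats::sd(raw[ok]) > 0)
    std[ok] <- (raw[ok] - mean(raw[ok])) / stats::sd(raw[ok])
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- sprintf("id%06d", seq_len(nrow(dosages)))
  data.frame(individual_id = ids, raw_score = raw, std_score = std,
             stringsAsFactors = FALSE)
}

#' Greedy LD clumping of candidate variants
#'
#' Variants are sorted by ascending p-value (ties broken by variant id) and
#' accepted greedily: a candidate is retained iff its pairwise r-squared
#' with every already-retained variant is below the threshold.
#'
#' @param variants data.frame with \code{variant_id} and \code{pvalue}.
#' @param r2 symmetric matrix of pairwise r-squared values in [0, 1], with
#'   dimnames matching the variant ids.
#' @param r2_threshold retention threshold (default 0.01; a "relaxed"
#'   sensitivity value of 0.1 is conventional).
#' @return character vector of retained variant ids, in acceptance order.
#' @export
ld_clump <- function(variants, r2, r2_threshold = 0.01) {
  stopifnot(all(is.finite(variants$pvalue)))
  ord <- order(variants$pvalue, variants$variant_id)
  ids <- variants$variant_id[ord]
  kept <- character(0)
  for (v in ids) {
    if (length(kept) == 0 || all(r2[v, kept] < r2_threshold))
      kept <- c(kept, v)
  }
  kept
}

#' First-stage instrument strength diagnostics
#'
#' Linear regression of the exposure on the standardized score plus
#' covariates; reports the score coefficient, its SE, the partial variance
#' in the exposure explained by the score given the covariates, and the
#' partial F statistic \code{(n - k - 2) R2p / (1 - R2p)} for k adjustment
#' covariates (which reduces to \code{(n - 2) R2 / (1 - R2)} with none).
#'
#' @param std_score standardized score vector.
#' @param exposure exposure vector (same length).
#' @param covariates optional data.frame or matrix of adjustment covariates.
#' @param label subset label carried into the result.
#' @param min_n refuse to fit below this size.
#' @return list of class \code{"instrument_fit"}: \code{label},
#'   \code{beta_zx}, \code{se_zx}, \code{r_squared} (partial), \code{f_statistic},
#'   \code{n}.
#' @export
instrument_strength <- function(std_score, exposure, covariates = NULL,
                                label = "all", min_n = 30) {
  ok <- stats::complete.cases(std_score, exposure)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  n <- sum(ok)
  if (n < min_n) stop("subset too small for a first-stage fit (n = ", n, ")",
                      call. = FALSE)
  y <- exposure[ok]
  z <- std_score[ok]
  if (is.null(covariates)) {
    x0 <- matrix(1, n, 1)
  } else {
    cv <- as.data.frame(covariates)[ok, , drop = FALSE]
    x0 <- stats::model.matrix(~ ., data = cv)
    x0 <- drop_aliased(x0)
  }
  x1 <- cbind(x0, score = z)
  f0 <- stats::lm.fit(x0, y)
  f1 <- stats::lm.fit(x1, y)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  r2p <- (rss0 - rss1) / rss0
  sigma2 <- rss1 / (n - ncol(x1))
  xtx_inv <- chol2inv(chol(crossprod(x1)))
  se <- sqrt(sigma2 * xtx_inv[ncol(x1), ncol(x1)])
  structure(list(label = label,
                 beta_zx = unname(f1$coefficients["score"]),
                 se_zx = se,
                 r_squared = r2p,
                 f_statistic = (n - ncol(x1)) * r2p / (1 - r2p),
                 n = n),
            class = "instrument_fit")
}

drop_aliased <- function(x) {
  q <- qr(x)
  if (q$rank < ncol(x)) {
    drop <- colnames(x)[q$pivot[(q$rank + 1):ncol(x)]]
    warning("dropping aliased covariate(s): ", paste(drop, collapse = ", "),
            call. = FALSE)
    x <- x[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  x
}

#' Characteristics across fifths of the genetic score
#'
#' Quintile boundaries are taken at the 20/40/60/80 percentiles of the score
#' within sex (the score distributions, and hence the fifths, are
#' sex-specific); ties spanning a boundary are resolved by stable sort
#' order. Continuous characteristics are summarised by the mean, binary or
#' logical ones by the percentage, each per fifth, together with the
#' top-minus-bottom gradient.
#'
#' @param std_score standardized score.
#' @param sex factor with levels \code{male}/\code{female}.
#' @param characteristics data.frame of characteristics to tabulate
#'   (numeric or logical columns).
#' @return data.frame: one row per characteristic x sex, columns
#'   \code{fifth1 ... fifth5} and \code{gradient}.
#' @export
fifths_table <- function(std_score, sex, characteristics) {
  stopifnot(nrow(characteristics) == length(std_score))
  fifth <- integer(length(std_score))
  for (s in levels(sex)) {
    i <- which(sex == s)
    r <- rank(std_score[i], ties.method = "first")
    fifth[i] <- floor((r - 1) * 5 / length(i)) + 1L
  }
  rows <- list()
  for (nm in names(characteristics)) {
    v <- characteristics[[nm]]
    binary <- is.logical(v) || all(v %in% c(0, 1, NA))
    v <- as.numeric(v)
    for (s in levels(sex)) {
      cell <- vapply(1:5, function(k) {
        m <- mean(v[sex == s & fifth == k], na.rm = TRUE)
        if (binary) 100 * m else m
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = nm, sex = s, statistic = if (binary) "%" else "mean",
        t(stats::setNames(cell, paste0("fifth", 1:5))),
        gradient = cell[5] - cell[1], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
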