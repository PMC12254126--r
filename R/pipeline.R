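#' Assemble and validate an analysis configuration
#'
#' A configuration names either a simulation block (arguments to
#' \code{\link{sim_params}}) or input paths (dosage TSV, weights TSV,
#' phenotype CSV) -- exactly one of the two -- plus the causes to analyse,
#' the age window, estimator toggles, and a seed.
#'
#' @param simulation list of \code{\link{sim_params}} arguments, or NULL.
#' @param inputs list with \code{dosages}, \code{weights}, \code{phenotypes}
#'   paths, or NULL.
#' @param causes cause labels to estimate (must exist in the hierarchy).
#' @param window main analysis age window.
#' @param estimators character subset of
#'   c("onesample", "mediation", "twosample", "nonlinear").
#' @param n_boot bootstrap resamples for the mediation interval.
#' @param q strata for non-linear MR.
#' @param n_pcs principal components entering the models as covariates.
#' @param seed run seed.
#' @return validated list of class \code{"analysis_config"}.
#' @export
analysis_config <- function(simulation = list(), inputs = NULL,
                            causes = c("all", "vascular_metabolic",
                                       "nonvascular_metabolic"),
                            window = c(35, 75),
                            estimators = c("onesample", "mediation"),
                            n_boot = 200, q = 10, n_pcs = 2, seed = 1L) {
  if (!is.null(simulation) && !is.null(inputs))
    stop("give either a simulation block or input paths, not both",
         call. = FALSE)
  if (is.null(simulation) && is.null(inputs))
    stop("give a simulation block or input paths", call. = FALSE)
  bad <- setdiff(causes, cause_hierarchy()$cause)
  if (length(bad))
    stop("unknown cause in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad_est <- setdiff(estimators,
                     c("onesample", "mediation", "twosample", "nonlinear"))
  if (length(bad_est))
    stop("unknown estimator: ", paste(bad_est, collapse = ", "),
         call. = FALSE)
  structure(list(simulation = simulation, inputs = inputs, causes = causes,
                 window = window, estimators = estimators, n_boot = n_boot,
                 q = q, n_pcs = n_pcs, seed = as.integer(seed)),
            class = "analysis_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config), f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: data (simulate or load),
#' exclusions, score construction, instrument diagnostics, one-sample MR by
#' cause with sex-specific Wald ratios pooled by inverse variance, and the
#' optional mediation / two-sample / non-linear stages. Reruns with an
#' identical configuration reproduce identical tables; every table carries
#' the configuration hash and seed as attributes.
#'
#' @param config an \code{\link{analysis_config}}.
#' @return list of class \code{"result_bundle"} with elements
#'   \code{forest}, \code{instrument}, \code{fifths}, \code{ledger},
#'   \code{mediation}, \code{twosample}, \code{nonlinear} (optional stages
#'   NULL when not requested), \code{truth}, \code{config},
#'   \code{config_hash}, and \code{log} (one line per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  t0 <- proc.time()[3]

  if (!is.null(config$simulation)) {
    params <- do.call(sim_params, c(config$simulation,
                                    list(seed = config$seed)))
    sim <- simulate_cohort(params)
    note("stage=data mode=simulate n=%d variants=%d elapsed=%.1fs",
         params$n_individuals, nrow(sim$panel), proc.time()[3] - t0)
  } else {
    sim <- load_cohort_inputs(config$inputs)
    note("stage=data mode=load n=%d variants=%d elapsed=%.1fs",
         nrow(sim$cohort), nrow(sim$panel), proc.time()[3] - t0)
  }

  ex <- apply_exclusions(sim$cohort, sim$flags)
  keep <- match(ex$analysis$individual_id, sim$cohort$individual_id)
  cohort <- ex$analysis
  dos <- sim$dosages[keep, , drop = FALSE]
  attr(dos, "counted_allele") <- attr(sim$dosages, "counted_allele")
  note("stage=exclusions kept=%d removed=%d", nrow(cohort),
       sum(ex$ledger$n_removed))

  pb <- sim$panel[sim$panel$trait == "bmi", ]
  pd <- sim$panel[sim$panel$trait == "diabetes", ]
  score_bmi <- compute_score(dos, pb)$std_score
  score_diab <- compute_score(dos, pd)$std_score
  pcs <- as.data.frame(cohort[, grep("^pc", names(cohort)), drop = FALSE])
  pcs <- pcs[, seq_len(min(config$n_pcs, ncol(pcs))), drop = FALSE]
  exposure <- cohort$bmi_measured
  records <- cohort[, c("entry_age", "exit_age", "died", "cause")]
  note("stage=scores n=%d", nrow(cohort))

  inst <- list()
  for (s in levels(cohort$sex)) {
    i <- cohort$sex == s
    inst[[s]] <- instrument_strength(score_bmi[i], exposure[i],
                                     covariates = pcs[i, , drop = FALSE],
                                     label = s)
  }
  inst_tab <- do.call(rbind, lapply(inst, function(f)
    data.frame(subset = f$label, beta_zx = f$beta_zx, se_zx = f$se_zx,
               r_squared = f$r_squared, f_statistic = f$f_statistic,
               n = f$n)))
  fifths <- fifths_table(score_bmi, cohort$sex, data.frame(
    bmi = exposure,
    diabetes = cohort$diabetes != "none",
    current_smoker = cohort$smoking == "current",
    any_activity = cohort$activity == "any",
    ancestry = cohort$ancestry_prop,
    entry_age = cohort$entry_age))
  note("stage=diagnostics r2=%s",
       paste(sprintf("%s=%.4f", inst_tab$subset, inst_tab$r_squared),
             collapse = " "))

  forest <- NULL
  if ("onesample" %in% config$estimators) {
    rows <- list()
    for (cc in config$causes) {
      per_sex <- list()
      for (s in levels(cohort$sex)) {
        i <- cohort$sex == s
        zy <- try(fit_cox(records[i, , drop = FALSE], score_bmi[i],
                          covariates = pcs[i, , drop = FALSE], cause = cc,
                          window = config$window, label = s), silent = TRUE)
        if (inherits(zy, "try-error")) next
        per_sex[[s]] <- wald_ratio(zy, inst[[s]],
                                   label = paste0(cc, ":", s))
        rows[[length(rows) + 1L]] <- forest_row(per_sex[[s]], cc, s,
                                                zy$n_events)
      }
      if (length(per_sex)) {
        pooled <- ivw_pool(per_sex, label = paste0(cc, ":pooled"))
        ev <- sum(vapply(rows, function(r)
          if (r$cause == cc) r$events else 0L, numeric(1)))
        rows[[length(rows) + 1L]] <- forest_row(pooled, cc, "pooled", ev)
      }
    }
    forest <- do.call(rbind, lapply(rows, as.data.frame))
    note("stage=onesample causes=%d", length(config$causes))
  }

  mediation <- NULL
  if ("mediation" %in% config$estimators) {
    med <- mediation_mr(score_bmi, score_diab, exposure, cohort$diabetes,
                        records, covariates = pcs, window = config$window,
                        bmi_variants = pb$variant_id,
                        diab_variants = pd$variant_id)
    ci <- bootstrap_proportion(score_bmi, score_diab, exposure,
                               cohort$diabetes, records, covariates = pcs,
                               window = config$window,
                               n_boot = config$n_boot, seed = config$seed)
    mediation <- data.frame(
      cause = "all",
      hr_total = exp(5 * med$loghr_total),
      hr_direct = exp(5 * med$loghr_direct),
      proportion_mediated = med$proportion,
      ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
      n_boot_used = ci$n_boot_used)
    note("stage=mediation proportion=%.3f boot=%d", med$proportion,
         ci$n_boot_used)
  }

  twosample <- NULL
  if ("twosample" %in% config$estimators) {
    bmi_dos <- dos[, pb$variant_id, drop = FALSE]
    summ <- per_snp_summaries(bmi_dos, exposure, records,
                              covariates = pcs, window = config$window)
    ivw <- ivw_2s(summ)
    wm <- weighted_median(summ, seed = config$seed)
    eg <- mr_egger(summ)
    twosample <- data.frame(
      estimator = c("ivw", "weighted_median", "egger_slope"),
      beta_iv = c(ivw$beta_iv, wm$beta_iv, eg$slope$beta_iv),
      se_iv = c(ivw$se_iv, wm$se_iv, eg$slope$se_iv),
      hr_scaled = c(ivw$hr_scaled, wm$hr_scaled, eg$slope$hr_scaled))
    attr(twosample, "egger_intercept") <- eg$intercept
    attr(twosample, "egger_intercept_p") <- eg$intercept_p
    note("stage=twosample variants=%d", nrow(summ))
  }

  nonlinear <- NULL
  if ("nonlinear" %in% config$estimators) {
    str_dr <- doubly_ranked_strata(exposure, score_bmi, q = config$q)
    nl <- stratum_mr(str_dr, cohort, score_bmi, exposure,
                     covariates = pcs, window = config$window)
    nc_age <- negative_control(str_dr, score_bmi, cohort$entry_age, "age")
    nc_sex <- negative_control(str_dr, score_bmi, cohort$sex, "sex")
    nonlinear <- list(strata = nl$table, heterogeneity = nl$heterogeneity,
                      trend = nl$trend, control_age = nc_age,
                      control_sex = nc_sex)
    note("stage=nonlinear q=%d Qp=%.3f", config$q, nl$heterogeneity$p)
  }

  bundle <- structure(list(
    forest = forest, instrument = inst_tab, fifths = fifths,
    ledger = ex$ledger, mediation = mediation, twosample = twosample,
    nonlinear = nonlinear,
    truth = if (!is.null(sim$truth)) sim$truth else NULL,
    config = config, config_hash = config_hash(config), log = log),
    class = "result_bundle")
  bundle
}

forest_row <- function(est, cause, subset, events) {
  list(cause = cause, subset = subset, beta_iv = est$beta_iv,
       se_iv = est$se_iv, hr_scaled = est$hr_scaled, ci_lo = est$ci_lo,
       ci_hi = est$ci_hi, events = as.numeric(events))
}

#' Write a result bundle as CSV tables plus a markdown summary
#'
#' Every present stage is written as a UTF-8 CSV stamped (in a leading
#' comment-free sidecar column-less file, \code{run_info.csv}) with the
#' configuration hash and seed; absent stages are omitted from the report,
#' never fabricated.
#'
#' @param bundle a \code{"result_bundle"} from \code{\link{run_pipeline}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
make_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(data.frame(config_hash = bundle$config_hash,
                seed = bundle$config$seed), "run_info")
  wr(bundle$instrument, "instrument_strength")
  wr(bundle$fifths, "fifths_table")
  wr(bundle$ledger, "exclusion_ledger")
  if (!is.null(bundle$forest)) wr(bundle$forest, "forest_table")
  if (!is.null(bundle$mediation)) wr(bundle$mediation, "mediation_table")
  if (!is.null(bundle$twosample)) wr(bundle$twosample, "twosample_table")
  if (!is.null(bundle$nonlinear)) {
    wr(bundle$nonlinear$strata, "stratum_table")
    wr(bundle$nonlinear$control_age, "negative_control_age")
    wr(bundle$nonlinear$control_sex, "negative_control_sex")
  }

  md <- c("# Analysis summary", "",
          sprintf("config hash: %s, seed: %d", bundle$config_hash,
                  bundle$config$seed), "",
          "## Instrument strength",
          md_table(bundle$instrument))
  if (!is.null(bundle$forest))
    md <- c(md, "", "## Forest table (HR per 5 kg/m2)",
            md_table(bundle$forest))
  if (!is.null(bundle$mediation))
    md <- c(md, "", "## Mediation through diabetes liability",
            md_table(bundle$mediation))
  if (!is.null(bundle$twosample))
    md <- c(md, "", "## Two-sample sensitivity estimators",
            md_table(bundle$twosample))
  if (!is.null(bundle$nonlinear))
    md <- c(md, "", "## Non-linear MR strata",
            md_table(bundle$nonlinear$strata))
  md <- c(md, "", "## Exclusion ledger", md_table(bundle$ledger))
  p <- file.path(out_dir, "summary.md")
  writeLines(md, p)
  invisible(c(paths, p))
}

md_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "),
                                         "|"))
  c(hdr, sep, rows)
}

#' Read an analysis configuration from a YAML file
#'
#' The YAML mirrors the \code{\link{analysis_config}} arguments: an optional
#' \code{simulation} mapping of \code{\link{sim_params}} arguments (or an
#' \code{inputs} mapping of file paths), plus \code{causes}, \code{window},
#' \code{estimators}, \code{n_boot}, \code{q}, \code{n_pcs}, \code{seed}.
#'
#' @param path YAML file path.
#' @return A validated \code{\link{analysis_config}}.
#' @export
read_analysis_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations",
         call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration field: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$window)) raw$window <- as.numeric(raw$window)
  do.call(analysis_config, raw)
}
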