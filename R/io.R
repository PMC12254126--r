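#' Write a simulated data set as plain-text files
#'
#' Emits the tabular interchange formats the pipeline reads back: a
#' tab-separated dosage matrix (individuals x variants, first column
#' \code{individual_id}), a weights TSV (\code{variant_id},
#' \code{effect_allele}, \code{other_allele}, \code{beta},
#' \code{allele_freq}, \code{trait}), and a phenotype/outcome CSV (one row
#' per individual, including the survival record and exclusion flags).
#'
#' @param sim a bundle from \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the three paths written.
#' @export
write_cohort_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pw <- file.path(dir, "weights.tsv")
  w <- data.frame(variant_id = sim$panel$variant_id,
                  effect_allele = sim$panel$effect_allele,
                  other_allele = sim$panel$other_allele,
                  beta = sim$panel$weight,
                  allele_freq = sim$panel$allele_freq,
                  trait = sim$panel$trait)
  utils::write.table(w, pw, sep = "\t", quote = FALSE, row.names = FALSE)

  pd <- file.path(dir, "dosages.tsv")
  d <- data.frame(individual_id = sim$cohort$individual_id,
                  sim$dosages, check.names = FALSE)
  utils::write.table(d, pd, sep = "\t", quote = FALSE, row.names = FALSE)

  pp <- file.path(dir, "phenotypes.csv")
  ph <- cbind(sim$cohort, sim$flags[, setdiff(names(sim$flags),
                                              "individual_id")])
  utils::write.csv(ph, pp, row.names = FALSE)
  invisible(c(weights = pw, dosages = pd, phenotypes = pp))
}

#' Load a cohort from the plain-text interchange files
#'
#' Counterpart of \code{\link{write_cohort_data}}; returns the same bundle
#' shape \code{\link{simulate_cohort}} produces (without \code{truth},
#' which only a simulation knows).
#'
#' @param inputs list with \code{weights}, \code{dosages},
#'   \code{phenotypes} paths.
#' @return list with \code{panel}, \code{dosages}, \code{cohort},
#'   \code{flags}.
#' @export
load_cohort_inputs <- function(inputs) {
  w <- utils::read.delim(inputs$weights, stringsAsFactors = FALSE)
  panel <- data.frame(variant_id = w$variant_id,
                      effect_allele = w$effect_allele,
                      other_allele = w$other_allele,
                      weight = w$beta, allele_freq = w$allele_freq,
                      trait = w$trait, stringsAsFactors = FALSE)
  class(panel) <- c("variant_panel", "data.frame")

  d <- utils::read.delim(inputs$dosages, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- d$individual_id
  dos <- as.matrix(d[, setdiff(names(d), "individual_id"), drop = FALSE])
  rownames(dos) <- ids
  attr(dos, "counted_allele") <- stats::setNames(panel$effect_allele,
                                                 panel$variant_id)

  ph <- utils::read.csv(inputs$phenotypes, stringsAsFactors = FALSE)
  ph$sex <- factor(ph$sex, levels = c("male", "female"))
  ph$diabetes <- factor(ph$diabetes,
                        levels = c("none", "undiagnosed", "diagnosed"))
  ph$district <- factor(ph$district)
  ph$smoking <- factor(ph$smoking, levels = c("never", "former", "current"))
  ph$activity <- factor(ph$activity, levels = c("none", "any"))
  flag_cols <- c("qc_fail", "age_ge_90", "implausible_anthropometry",
                 "uncertain_linkage")
  flags <- cbind(data.frame(individual_id = ph$individual_id),
                 ph[, intersect(flag_cols, names(ph)), drop = FALSE])
  cohort <- ph[, setdiff(names(ph), flag_cols), drop = FALSE]
  list(panel = panel, dosages = dos, cohort = cohort, flags = flags)
}
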