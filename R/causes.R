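#' Hierarchical cause-of-death classification
#'
#' The mortality outcome is a tree: every death is labelled with a leaf
#' cause, and analyses may target any node (a node's events are the union
#' of its leaves' events). The two top branches separate vascular-metabolic
#' deaths (vascular with cardiac/cerebrovascular/other subtypes, renal,
#' hepatobiliary, acute diabetic crises) from non-vascular-metabolic deaths
#' (cancer, respiratory, infective, external/other).
#'
#' @return data.frame with columns \code{cause} and \code{parent}
#'   (\code{NA} for the root, \code{"all"}).
#' @export
cause_hierarchy <- function() {
  data.frame(
    cause = c("all",
              "vascular_metabolic", "nonvascular_metabolic",
              "vascular", "renal", "hepatobiliary", "acute_diabetic_crisis",
              "cardiac", "cerebrovascular", "other_vascular",
              "cancer", "respiratory", "infective", "external_other"),
    parent = c(NA,
               "all", "all",
               "vascular_metabolic", "vascular_metabolic",
               "vascular_metabolic", "vascular_metabolic",
               "vascular", "vascular", "vascular",
               "nonvascular_metabolic", "nonvascular_metabolic",
               "nonvascular_metabolic", "nonvascular_metabolic"),
    stringsAsFactors = FALSE
  )
}

#' Leaf causes of the mortality hierarchy
#' @return character vector of causes with no children.
#' @export
cause_leaves <- function() {
  h <- cause_hierarchy()
  setdiff(h$cause, h$parent)
}

#' Ancestor chain of a cause (self first, root last)
#' @param cause a cause label present in the hierarchy.
#' @return character vector from \code{cause} up to \code{"all"}.
#' @export
cause_ancestors <- function(cause) {
  h <- cause_hierarchy()
  if (!cause %in% h$cause) stop("unknown cause: ", cause, call. = FALSE)
  out <- cause
  cur <- cause
  repeat {
    par <- h$parent[match(cur, h$cause)]
    if (is.na(par)) break
    out <- c(out, par)
    cur <- par
  }
  out
}

# TRUE where a leaf label (or NA for survivors) falls under the target node.
cause_matches <- function(labels, target) {
  if (target == "all") return(!is.na(labels) & labels != "none")
  h <- cause_hierarchy()
  keep <- vapply(setdiff(h$cause, "all"),
                 function(cc) target %in% cause_ancestors(cc), logical(1))
  !is.na(labels) & labels %in% names(keep)[keep]
}

#' Roll leaf-cause death counts up the hierarchy
#'
#' @param labels leaf cause labels for deaths (\code{NA} or \code{"none"}
#'   for survivors/censored records).
#' @return data.frame of \code{cause} and \code{n_events}, one row per node,
#'   where every internal node's count is the sum of its children.
#' @export
cause_rollup <- function(labels) {
  h <- cause_hierarchy()
  data.frame(
    cause = h$cause,
    n_events = vapply(h$cause, function(cc) sum(cause_matches(labels, cc)),
                      integer(1)),
    row.names = NULL
  )
}

# Death-certificate mix used by the generator: leaf probabilities conditional
# on death, patterned on ~13k observed deaths (the split of the vascular
# subtotal into cardiac/cerebrovascular/other is a stand-in choice).
default_cause_mix <- function() {
  n <- c(cardiac = 2100, cerebrovascular = 900, other_vascular = 451,
         renal = 2034, hepatobiliary = 1069, acute_diabetic_crisis = 557,
         cancer = 2107, respiratory = 2050, infective = 811,
         external_other = 987)
  n / sum(n)
}
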