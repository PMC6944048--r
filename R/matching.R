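#' Greedy 1:1 propensity-score caliper matching
#'
#' Cases are processed in descending score order (`"largest"`), ascending
#' order (`"smallest"`) or a seeded random permutation (`"random"`). Each case
#' is matched to the not-yet-used control with the smallest absolute score
#' difference and the pair is accepted only if that difference does not exceed
#' the caliper (probability scale); unmatched cases are dropped. With a seed,
#' controls are shuffled once so that ties between equidistant controls are
#' broken by the lowest post-shuffle index; without a seed the original
#' control order breaks ties.
#'
#' @param case_scores,control_scores Named numeric vectors of propensity
#'   scores (names are sample IDs).
#' @param caliper Maximum within-pair score difference (>= 0).
#' @param order_method `"largest"`, `"smallest"` or `"random"`.
#' @param seed Integer seed for the processing/tie-break permutations, or
#'   `NULL` for the deterministic unshuffled order.
#' @return An object of class `psm_pairs`: a tibble with columns `case_id`,
#'   `control_id`, `ps_case`, `ps_control`, `ps_diff`, carrying attributes
#'   `caliper`, `order_method`, `seed`.
#' @export
greedy_caliper_match <- function(case_scores, control_scores, caliper,
                                 order_method = c("largest", "smallest",
                                                  "random"),
                                 seed = NULL) {
  order_method <- match.arg(order_method)
  assert_that(caliper >= 0, "caliper must be >= 0")
  if (is.null(names(case_scores))) {
    names(case_scores) <- sprintf("case%d", seq_along(case_scores))
  }
  if (is.null(names(control_scores))) {
    names(control_scores) <- sprintf("ctrl%d", seq_along(control_scores))
  }
  empty <- tibble::tibble(case_id = character(), control_id = character(),
                          ps_case = numeric(), ps_control = numeric(),
                          ps_diff = numeric())
  if (length(case_scores) == 0 || length(control_scores) == 0) {
    warning("empty case or control set; returning an empty matching",
            call. = FALSE)
    return(new_psm_pairs(empty, caliper, order_method, seed))
  }
  if (is.null(seed)) {
    case_perm <- seq_along(case_scores)
    ctrl_perm <- seq_along(control_scores)
  } else {
    case_perm <- with_seed(derive_seed(seed, 21L),
                           sample(seq_along(case_scores)))
    ctrl_perm <- with_seed(derive_seed(seed, 22L),
                           sample(seq_along(control_scores)))
  }
  case_idx <- switch(order_method,
    largest = case_perm[order(case_scores[case_perm], decreasing = TRUE)],
    smallest = case_perm[order(case_scores[case_perm])],
    random = case_perm
  )
  m <- greedy_match_cpp(unname(case_scores[case_idx]),
                        unname(control_scores[ctrl_perm]), caliper)
  hit <- m > 0
  ci <- case_idx[hit]
  ki <- ctrl_perm[m[hit]]
  pairs <- tibble::tibble(
    case_id = names(case_scores)[ci],
    control_id = names(control_scores)[ki],
    ps_case = unname(case_scores[ci]),
    ps_control = unname(control_scores[ki]),
    ps_diff = abs(unname(case_scores[ci]) - unname(control_scores[ki]))
  )
  stopifnot(all(pairs$ps_diff <= caliper + 1e-12),
            !anyDuplicated(pairs$case_id), !anyDuplicated(pairs$control_id))
  new_psm_pairs(pairs, caliper, order_method, seed)
}

new_psm_pairs <- function(pairs, caliper, order_method, seed) {
  structure(pairs, caliper = caliper, order_method = order_method,
            seed = seed, class = c("psm_pairs", class(pairs)))
}

#' @export
print.psm_pairs <- function(x, ...) {
  cat(sprintf("<psm_pairs> %d pairs | caliper %.3g, order '%s'\n",
              nrow(x), attr(x, "caliper"), attr(x, "order_method")))
  NextMethod()
}

#' Paired homogeneity tests on a matching
#'
#' Paired t and Wilcoxon signed-rank tests on the matched cases' and controls'
#' propensity scores; both p-values large means the matched groups are
#' demographically homogeneous.
#'
#' @param pairs A `psm_pairs` object.
#' @return A list with `p_t` and `p_wilcoxon` (both `NA` for < 2 pairs).
#' @export
balance_tests <- function(pairs) {
  if (nrow(pairs) < 2) {
    return(list(p_t = NA_real_, p_wilcoxon = NA_real_))
  }
  list(p_t = paired_t_test(pairs$ps_case, pairs$ps_control),
       p_wilcoxon = wilcoxon_signed_rank(pairs$ps_case, pairs$ps_control))
}

#' Standardized mean differences of covariates between cases and controls
#'
#' @param cohort Tibble with `sample_id`, covariate columns and `status`.
#' @param pairs Optional `psm_pairs`; if given, the SMD is computed on the
#'   matched subsample.
#' @param covariates Covariate column names.
#' @return A tibble with columns `covariate`, `smd` (absolute value).
#' @export
covariate_balance <- function(cohort, pairs = NULL,
                              covariates = c("age", "bmi")) {
  if (!is.null(pairs)) {
    cases <- cohort[match(pairs$case_id, cohort$sample_id), ]
    ctrls <- cohort[match(pairs$control_id, cohort$sample_id), ]
  } else {
    cases <- dplyr::filter(cohort, .data$status == "case")
    ctrls <- dplyr::filter(cohort, .data$status == "control")
  }
  tibble::tibble(
    covariate = covariates,
    smd = vapply(covariates,
                 function(v) abs(smd(cases[[v]], ctrls[[v]])), numeric(1))
  )
}
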