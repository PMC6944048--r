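#' Estimate a propensity-score model from demographic covariates
#'
#' Unpenalized logistic regression of case status on sex, age and BMI:
#' \eqn{p(\chi_i) = \mathrm{logit}^{-1}(\gamma_0 + \gamma_1 sex_i +
#' \gamma_2 age_i + \gamma_3 BMI_i)}. Perfect separation is flagged and the
#' coefficients capped so scores stay inside (0, 1).
#'
#' @param cohort Tibble with columns `sex`, `age`, `bmi` and `status`
#'   (`"case"`/`"control"`; other statuses are dropped).
#' @return A `psm_logit` fit (subclass `psm_propensity`) over
#'   (sex, age, bmi).
#' @export
estimate_propensity <- function(cohort) {
  d <- dplyr::filter(cohort, .data$status %in% c("case", "control"))
  assert_that(any(d$status == "case") && any(d$status == "control"),
              "both cases and controls are required")
  assert_that(all(stats::complete.cases(d[, c("sex", "age", "bmi")])),
              "sex, age and bmi must be complete")
  x <- as.matrix(d[, c("sex", "age", "bmi")])
  fit <- fit_logit_glm(x, as.integer(d$status == "case"),
                       penalty = "none", unpenalized = colnames(x))
  class(fit) <- c("psm_propensity", class(fit))
  fit
}

#' Propensity scores for a cohort
#' @param model A fit from [estimate_propensity()].
#' @param cohort Tibble with `sample_id`, `sex`, `age`, `bmi`.
#' @return Named numeric vector of scores in (0, 1).
#' @export
propensity_scores <- function(model, cohort) {
  s <- predict(model, as.matrix(cohort[, c("sex", "age", "bmi")]))
  stats::setNames(s, cohort$sample_id)
}
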