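#' Simulation configuration for synthetic case-control cohorts
#'
#' Defines the data-generating conditions for [simulate_cohort()]: genotypes
#' in Hardy-Weinberg equilibrium with uniform minor allele frequencies,
#' demographics with a tunable genetic (heritable) component in BMI, and a
#' logistic disease model mixing direct SNP effects with SNP effects mediated
#' entirely through BMI. Defaults emulate a population-based type 2 diabetes
#' case-control cohort: about 5,000 subjects, case:control near 1:3, cases
#' older and heavier than controls.
#'
#' @param n_samples Number of subjects.
#' @param n_snps Number of SNPs.
#' @param maf_range Length-2 vector; per-SNP minor allele frequencies are
#'   drawn uniformly from this interval, which must lie within (0, 0.5].
#' @param n_direct_causal Number of SNPs with a direct log-odds effect on
#'   disease.
#' @param n_bmi_causal Number of SNPs affecting disease only through BMI
#'   (zero direct coefficient).
#' @param beta_direct Per-allele log-odds effect of each direct-causal SNP.
#' @param b_bmi Per-allele BMI effect (kg/m^2) of each BMI-causal SNP. The
#'   default `NA` derives the value so that the genetic fraction of BMI
#'   variance equals `h2_bmi` while the total BMI standard deviation stays at
#'   `bmi_mean_sd[2]`. If supplied explicitly, the environmental variance is
#'   scaled so the genetic fraction still equals `h2_bmi` (the total SD is
#'   then implied, not `bmi_mean_sd[2]`).
#' @param h2_bmi Fraction in \[0, 1) of BMI variance that is genetic.
#' @param age_mean_sd,bmi_mean_sd Length-2 vectors (mean, SD) of the Normal
#'   age and BMI distributions. Defaults are the cohort-wide values
#'   51.44 +/- 8.85 years and 24.47 +/- 3.06 kg/m^2.
#' @param sex_prob Probability that sex = 1 (male).
#' @param gamma_demo Named length-3 vector of log-odds effects of
#'   (sex, age, bmi) on disease. Defaults are chosen so that, at the default
#'   prevalence, simulated cases are about 6 years older and 1.5 kg/m^2
#'   heavier than controls with a modest male excess.
#' @param intercept Baseline log-odds of disease. The default `NA` calibrates
#'   the intercept at simulation time so the population case probability
#'   averages `prevalence`.
#' @param prevalence Target mean case probability used when `intercept` is
#'   `NA`. The default yields an analyzed (case + control, excluding the
#'   intermediate stratum) case fraction near 0.26.
#' @param intermediate_rate Fraction of non-cases given intermediate
#'   ("prediabetic") clinical values; these subjects classify as excluded.
#' @param missing_rate Probability that a genotype call is missing.
#' @param snps_per_gene SNPs per synthetic gene in the annotation map.
#' @param seed Integer RNG seed; fixing (config, seed) makes every output
#'   bit-reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 500, n_snps = 50, seed = 1)
#' cfg$maf_range
sim_config <- function(n_samples = 5000,
                       n_snps = 1000,
                       maf_range = c(0.05, 0.5),
                       n_direct_causal = 20,
                       n_bmi_causal = 20,
                       beta_direct = 0.4,
                       b_bmi = NA_real_,
                       h2_bmi = 0.4,
                       age_mean_sd = c(51.44, 8.85),
                       bmi_mean_sd = c(24.47, 3.06),
                       sex_prob = 0.472,
                       gamma_demo = c(sex = 0.27, age = 0.077, bmi = 0.155),
                       intercept = NA_real_,
                       prevalence = 0.23,
                       intermediate_rate = 0.15,
                       missing_rate = 0.01,
                       snps_per_gene = 5,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    n_direct_causal = as.integer(n_direct_causal),
    n_bmi_causal = as.integer(n_bmi_causal),
    beta_direct = beta_direct, b_bmi = b_bmi, h2_bmi = h2_bmi,
    age_mean_sd = as.numeric(age_mean_sd),
    bmi_mean_sd = as.numeric(bmi_mean_sd),
    sex_prob = sex_prob,
    gamma_demo = stats::setNames(as.numeric(gamma_demo),
                                 c("sex", "age", "bmi")),
    intercept = intercept, prevalence = prevalence,
    intermediate_rate = intermediate_rate,
    missing_rate = missing_rate,
    snps_per_gene = as.integer(snps_per_gene),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_samples >= 1 && cfg$n_snps >= 0,
              "n_samples must be >= 1 and n_snps >= 0")
  assert_that(length(cfg$maf_range) == 2 &&
                cfg$maf_range[1] > 0 && cfg$maf_range[2] <= 0.5 &&
                cfg$maf_range[1] <= cfg$maf_range[2],
              "maf_range must be an increasing pair within (0, 0.5]")
  assert_that(cfg$n_direct_causal >= 0 && cfg$n_bmi_causal >= 0 &&
                cfg$n_direct_causal + cfg$n_bmi_causal <= cfg$n_snps,
              "causal SNP counts must be nonnegative and sum to at most n_snps")
  assert_that(cfg$h2_bmi >= 0 && cfg$h2_bmi < 1, "h2_bmi must be in [0, 1)")
  assert_that(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
              "missing_rate must be in [0, 1)")
  assert_that(cfg$sex_prob >= 0 && cfg$sex_prob <= 1,
              "sex_prob must be a probability")
  assert_that(cfg$intermediate_rate >= 0 && cfg$intermediate_rate < 1,
              "intermediate_rate must be in [0, 1)")
  if (cfg$h2_bmi == 0 && isTRUE(!is.na(cfg$b_bmi) && cfg$b_bmi != 0)) {
    stop("h2_bmi = 0 contradicts a nonzero b_bmi", call. = FALSE)
  }
  if (cfg$h2_bmi > 0 && cfg$n_bmi_causal == 0) {
    stop("h2_bmi > 0 requires n_bmi_causal >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d samples x %d SNPs, MAF U(%.2f, %.2f), missing %.1f%%\n",
              x$n_samples, x$n_snps, x$maf_range[1], x$maf_range[2],
              100 * x$missing_rate))
  cat(sprintf("  causal: %d direct (beta %.2f), %d BMI-mediated (h2_bmi %.2f)\n",
              x$n_direct_causal, x$beta_direct, x$n_bmi_causal, x$h2_bmi))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
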