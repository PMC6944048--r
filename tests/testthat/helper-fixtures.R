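# Shared fixtures, all generated in code under fixed seeds.

# Small cohort with a real confounding structure, reused by matching and
# pipeline tests.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(
        n_samples = 900, n_snps = 80, n_direct_causal = 6, n_bmi_causal = 6,
        missing_rate = 0.01, seed = 42
      ))
    }
    cache
  }
})

# Analyzed (case/control) subset of a cohort tibble.
analyzed_cohort <- function(ch) {
  dplyr::filter(ch$cohort, status %in% c("case", "control"))
}

# Toy logistic data with two informative predictors plus covariates.
toy_logit_data <- function(n = 200, seed = 1) {
  psmsnp:::with_seed(seed, {
    x <- cbind(a = rnorm(n), b = rnorm(n))
    eta <- -0.3 + 1.2 * x[, "a"] - 0.8 * x[, "b"]
    y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
    list(x = x, y = y)
  })
}

# Cached heavier computation for the central-phenomenon checks: per-seed
# matched vs unmatched evaluation under the stated simulation settings.
phenomenon_cache <- new.env(parent = emptyenv())

phenomenon_results <- function(n_seeds = 10) {
  key <- paste0("res", n_seeds)
  if (!is.null(phenomenon_cache[[key]])) return(phenomenon_cache[[key]])
  res <- purrr::map(seq_len(n_seeds), function(s) run_phenomenon_seed(s))
  out <- list(
    summary = dplyr::bind_rows(purrr::map(res, "summary")),
    group5 = dplyr::bind_rows(purrr::map(res, "group5"))
  )
  phenomenon_cache[[key]] <- out
  out
}

# One seed of the scaled-down matched-vs-unmatched comparison: n = 2000,
# 1000 SNPs, 20 direct-causal, 20 BMI-mediated, h2_bmi = 0.4; one set size
# (200), two selectors (lasso, en), groups {1, 3, 5}, two predictors.
run_phenomenon_seed <- function(s) {
  ch <- simulate_cohort(sim_config(
    n_samples = 2000, n_snps = 1000, n_direct_causal = 20,
    n_bmi_causal = 20, h2_bmi = 0.4, seed = 1000 + s
  ))
  qc <- apply_qc(ch$genotypes)
  coh <- analyzed_cohort(ch)
  coh <- coh[coh$sample_id %in% rownames(qc$genotypes), ]

  sweep <- run_sweep(coh, sweep_config(
    caliper_grid = seq(0, 1, by = 0.02), n_experiments = 10,
    methods = "random", seed = 1000 + s
  ))
  sel <- select_caliper(sweep, summary = "max")
  mc <- matched_cohort(coh, sweep, sel$caliper, sel$method, seed = 1000 + s)

  variants <- list(
    unmatched = list(genotypes = qc$genotypes, cohort = coh,
                     split = train_test_split(coh, seed = 1000 + s)),
    matched = list(genotypes = qc$genotypes, cohort = mc$cohort,
                   split = train_test_split(mc$cohort, seed = 1000 + s,
                                            pairs = mc$pairs))
  )
  sets <- purrr::imap(variants, function(v, vn) {
    rows <- match(v$split$train_ids, rownames(v$genotypes))
    crows <- match(v$split$train_ids, v$cohort$sample_id)
    scan <- single_snp_scan(v$genotypes[rows, , drop = FALSE],
                            v$cohort$status[crows],
                            v$cohort[crows, c("sex", "age", "bmi")])
    list(build_kare_set(scan, 200))
  })
  grid <- run_grid(variants, sets,
                   selection_methods = c("lasso", "en"),
                   groups = c(1, 3, 5),
                   prediction_methods = c("lasso", "en"),
                   seed = 1000 + s)
  best <- best_rows(grid)
  summary <- tibble::tibble(
    seed = s,
    best_delta_unmatched =
      best$delta[best$cohort_variant == "unmatched"],
    best_delta_matched = best$delta[best$cohort_variant == "matched"],
    auc_cov_unmatched =
      best$auc_covariates[best$cohort_variant == "unmatched"],
    auc_cov_matched = best$auc_covariates[best$cohort_variant == "matched"]
  )
  # causal-recovery: a SNP reaches group 5 only by entering the candidate
  # set and being selected in all five folds; rates are over the full
  # QC-surviving panel (planted causal vs null SNPs)
  counts <- grid_stability(grid)[[
    paste("unmatched", sets$unmatched[[1]]$name, "lasso", sep = "|")]]
  g5 <- counts$rsid[counts$count >= 5]
  panel <- colnames(qc$genotypes)
  causal_panel <- intersect(ch$truth$direct_causal, panel)
  null_panel <- setdiff(panel, c(ch$truth$direct_causal,
                                 ch$truth$bmi_causal))
  group5 <- tibble::tibble(
    seed = s,
    n_causal = length(causal_panel), n_null = length(null_panel),
    causal_g5 = length(intersect(causal_panel, g5)),
    null_g5 = length(intersect(null_panel, g5))
  )
  list(summary = summary, group5 = group5)
}
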