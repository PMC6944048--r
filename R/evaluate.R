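#' Delta-AUC: the pure additive contribution of SNPs
#'
#' Difference between the SNP-plus-covariates and covariates-only test AUCs,
#' rounded to reporting precision.
#'
#' @param auc_covariates Test AUC of the covariate-only model.
#' @param auc_snps_covariates Test AUC of the SNPs + covariates model.
#' @param digits Reporting precision (default 4 decimals).
#' @return `round(auc_snps_covariates - auc_covariates, digits)`.
#' @export
#' @examples
#' delta_auc(0.5379, 0.6449)  # 0.107
delta_auc <- function(auc_covariates, auc_snps_covariates, digits = 4) {
  round(auc_snps_covariates - auc_covariates, digits)
}

#' Fit prediction models and evaluate the SNP contribution on the test set
#'
#' Fits (a) a covariates-only logistic model and (b) a SNPs + covariates model
#' on the training data, then computes both test-set AUCs and their
#' difference. The SNP model uses LASSO at the CV-minimum lambda, elastic net
#' (mixing weight `en_alpha`) at the one-standard-error lambda, or stepwise
#' AUC selection followed by an unpenalized fit; covariates are never
#' penalized.
#'
#' @param train,test Lists from [model_frame()] (fields `x`, `covs`, `y`).
#' @param group_rsids SNPs of the stability group to offer the model (subset
#'   of the columns of `train$x`). An empty group yields delta = 0, flagged.
#' @param prediction_method `"slr"`, `"lasso"` or `"en"`.
#' @param en_alpha Elastic-net mixing weight.
#' @param seed Seed for inner CV / stepwise splits.
#' @param ... Passed to [stepwise_auc_select()] for `"slr"`.
#' @return A one-row tibble: `group_size`, `prediction_method`,
#'   `auc_covariates`, `auc_snps_covariates`, `delta`, `n_train`, `n_test`,
#'   `n_snps_used`, `empty_group`.
#' @export
fit_and_evaluate <- function(train, test, group_rsids,
                             prediction_method = c("lasso", "en", "slr"),
                             en_alpha = 0.5, seed = 1L, ...) {
  prediction_method <- match.arg(prediction_method)
  cov_fit <- fit_logit_glm(train$covs, train$y, "none",
                           unpenalized = colnames(train$covs))
  auc_cov <- auc(predict(cov_fit, test$covs), test$y)$auc
  group_rsids <- intersect(group_rsids, colnames(train$x))
  if (length(group_rsids) == 0) {
    return(tibble::tibble(
      group_size = 0L, prediction_method = prediction_method,
      auc_covariates = auc_cov, auc_snps_covariates = auc_cov,
      delta = 0, n_train = length(train$y), n_test = length(test$y),
      n_snps_used = 0L, empty_group = TRUE
    ))
  }
  xtr <- train$x[, group_rsids, drop = FALSE]
  xte <- test$x[, group_rsids, drop = FALSE]
  if (prediction_method == "slr") {
    sel <- stepwise_auc_select(xtr, train$covs, train$y, seed = seed, ...)
    fit <- fit_logit_glm(cbind(train$covs, xtr[, sel, drop = FALSE]),
                         train$y, "none", unpenalized = colnames(train$covs))
    scores <- predict(fit, cbind(test$covs, xte[, sel, drop = FALSE]))
    n_used <- length(sel)
  } else {
    X <- cbind(xtr, train$covs)
    alpha <- if (prediction_method == "lasso") 1 else en_alpha
    rule <- if (prediction_method == "lasso") "min" else "one_se"
    cv <- cv_select_lambda(X, train$y, k_folds = 5, rule = rule,
                           alpha = alpha, unpenalized = colnames(train$covs),
                           seed = seed)
    fit <- fit_logistic(
      X, train$y,
      penalty = if (prediction_method == "lasso") "l1" else "elastic_net",
      lambda1 = cv$lambda1, lambda2 = cv$lambda2,
      unpenalized = colnames(train$covs))
    scores <- predict(fit, cbind(xte, test$covs))
    n_used <- sum(fit$coefficients[group_rsids] != 0)
  }
  auc_snp <- auc(scores, test$y)$auc
  tibble::tibble(
    group_size = length(group_rsids),
    prediction_method = prediction_method,
    auc_covariates = auc_cov, auc_snps_covariates = auc_snp,
    delta = auc_snp - auc_cov,
    n_train = length(train$y), n_test = length(test$y),
    n_snps_used = as.integer(n_used), empty_group = FALSE
  )
}

#' Evaluate every (SNP set, selector, group, predictor) combination
#'
#' For each cohort variant and candidate SNP set: runs CV stability selection
#' under each selection method on the training data, forms the nested
#' appearance-count groups, fits each prediction model per group, and records
#' the covariate-only AUC, the SNPs + covariates AUC and their delta on the
#' held-out test set.
#'
#' @param variants Named list of cohort variants, each a list with
#'   `genotypes`, `cohort` (tibble with `sample_id`, `sex`, `age`, `bmi`,
#'   `status`) and `split` (from [train_test_split()]).
#' @param snp_sets List of [snp_set()] objects (shared across variants;
#'   per-variant lists are supported as a named list of lists).
#' @param selection_methods,prediction_methods Subsets of
#'   `c("slr", "lasso", "en")`.
#' @param groups Group indices to evaluate (subset of 1..k_folds).
#' @param k_folds Stability-selection folds (default 5).
#' @param en_alpha Elastic-net mixing weight.
#' @param seed Base seed.
#' @param ... Passed to the stepwise selector.
#' @return A tibble of class `psm_grid` with one row per evaluated cell:
#'   `cohort_variant`, `snp_set`, `selection_method`, `group`,
#'   `prediction_method`, AUCs, `delta`, sizes and `seed`.
#' @export
run_grid <- function(variants, snp_sets,
                     selection_methods = c("slr", "lasso", "en"),
                     groups = 1:5,
                     prediction_methods = c("slr", "lasso", "en"),
                     k_folds = 5, en_alpha = 0.5, seed = 1L, ...) {
  rows <- list()
  stability <- list()
  per_variant_sets <- !is.null(names(snp_sets)) &&
    setequal(names(snp_sets), names(variants))
  for (vn in names(variants)) {
    v <- variants[[vn]]
    sets <- if (per_variant_sets) snp_sets[[vn]] else snp_sets
    for (set in sets) {
      rsids <- intersect(set$rsids, colnames(v$genotypes))
      train <- model_frame(v$genotypes, v$cohort, v$split$train_ids, rsids)
      test <- model_frame(v$genotypes, v$cohort, v$split$test_ids, rsids,
                          impute_means = train$impute_means)
      for (sm in selection_methods) {
        counts <- tryCatch(
          cv_stability_select(train$x, train$covs, train$y, method = sm,
                              k_folds = k_folds, en_alpha = en_alpha,
                              seed = derive_seed(seed, 61L,
                                                 match(sm, c("slr", "lasso",
                                                             "en"))),
                              ...),
          error = function(e) {
            warning(sprintf("stability selection failed (%s/%s/%s): %s",
                            vn, set$name, sm, e$message), call. = FALSE)
            NULL
          })
        if (is.null(counts)) next
        stability[[paste(vn, set$name, sm, sep = "|")]] <- counts
        grp_tbl <- form_groups(counts, n_groups = k_folds)
        for (g in groups) {
          grs <- grp_tbl$rsids[[g]]
          for (pm in prediction_methods) {
            ev <- tryCatch(
              fit_and_evaluate(train, test, grs, prediction_method = pm,
                               en_alpha = en_alpha,
                               seed = derive_seed(seed, 62L, g,
                                                  match(pm, c("slr", "lasso",
                                                              "en"))),
                               ...),
              error = function(e) {
                warning(sprintf("evaluation failed (%s/%s/%s/g%d/%s): %s",
                                vn, set$name, sm, g, pm, e$message),
                        call. = FALSE)
                NULL
              })
            if (is.null(ev)) next
            rows[[length(rows) + 1]] <- dplyr::bind_cols(
              tibble::tibble(cohort_variant = vn, snp_set = set$name,
                             selection_method = sm, group = g),
              ev, tibble::tibble(seed = seed)
            )
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  # per-(variant, set, selector) stability counts, keyed "variant|set|method"
  attr(out, "stability") <- stability
  class(out) <- c("psm_grid", class(out))
  out
}

#' Stability counts recorded during [run_grid()]
#' @param grid A `psm_grid`.
#' @return Named list of `stability_counts`, keyed `variant|set|method`.
#' @export
grid_stability <- function(grid) {
  attr(grid, "stability")
}

#' Best row per SNP set (and cohort variant)
#'
#' Extracts, per (cohort variant, SNP set), the row with the highest
#' SNPs + covariates AUC; ties go to the smaller group index.
#'
#' @param grid A `psm_grid` from [run_grid()].
#' @return A tibble with one row per (cohort_variant, snp_set).
#' @export
best_rows <- function(grid) {
  grid |>
    dplyr::group_by(.data$cohort_variant, .data$snp_set) |>
    dplyr::arrange(dplyr::desc(.data$auc_snps_covariates), .data$group,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Write the evaluation grid as TSV (delta at 4-decimal precision)
#' @param grid A `psm_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  out <- dplyr::mutate(grid,
                       dplyr::across(c("auc_covariates",
                                       "auc_snps_covariates", "delta"),
                                     ~ round(.x, 4)))
  readr::write_tsv(out, path)
  invisible(path)
}
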