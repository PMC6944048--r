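#' Cross-validation stability selection of SNPs
#'
#' Splits the training data into `k_folds` stratified folds; for each fold,
#' runs the chosen selector on that fold's training portion (the other
#' k - 1 folds) and records which SNPs it selects. LASSO selects the SNPs
#' with nonzero coefficients at the CV-minimum lambda, elastic net (mixing
#' weight `en_alpha`) at the one-standard-error lambda, and `"slr"` uses
#' [stepwise_auc_select()]. Demographic covariates are always in the model
#' and never counted.
#'
#' @param x SNP dosage matrix (training samples, imputed) — typically the
#'   columns of one candidate [snp_set()].
#' @param covs Covariate matrix (sex, age, bmi).
#' @param y Binary outcome.
#' @param method `"slr"`, `"lasso"` or `"en"`.
#' @param k_folds Number of folds (default 5).
#' @param en_alpha Elastic-net mixing weight (default 0.5).
#' @param seed Seed for fold assignment and fold-level selectors.
#' @param ... Passed to [stepwise_auc_select()] for `method = "slr"`.
#' @return An object of class `stability_counts`: tibble with `rsid` and
#'   `count` (0..k_folds) for every input SNP, with attributes `method` and
#'   `k_folds`.
#' @export
cv_stability_select <- function(x, covs, y,
                                method = c("lasso", "en", "slr"),
                                k_folds = 5, en_alpha = 0.5, seed = 1L, ...) {
  method <- match.arg(method)
  x <- as_pred_matrix(x)
  rsids <- colnames(x) %||% character()
  counts <- stats::setNames(integer(length(rsids)), rsids)
  if (length(rsids) > 0) {
    fold <- stratified_folds(y, k_folds, derive_seed(seed, 51L))
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      sel <- tryCatch(
        select_in_fold(x[tr, , drop = FALSE], covs[tr, , drop = FALSE],
                       y[tr], method, en_alpha,
                       seed = derive_seed(seed, 52L, f), ...),
        error = function(e) {
          warning(sprintf("fold %d selector failed: %s", f, e$message),
                  call. = FALSE)
          character()
        })
      counts[sel] <- counts[sel] + 1L
    }
  }
  structure(tibble::tibble(rsid = rsids, count = unname(counts)),
            method = method, k_folds = k_folds,
            class = c("stability_counts", "tbl_df", "tbl", "data.frame"))
}

select_in_fold <- function(x, covs, y, method, en_alpha, seed, ...) {
  if (method == "slr") {
    return(as.character(stepwise_auc_select(x, covs, y, seed = seed, ...)))
  }
  X <- cbind(x, covs)
  alpha <- if (method == "lasso") 1 else en_alpha
  rule <- if (method == "lasso") "min" else "one_se"
  cv <- cv_select_lambda(X, y, k_folds = 5, rule = rule, alpha = alpha,
                         unpenalized = colnames(covs), seed = seed)
  fit <- fit_logistic(X, y,
                      penalty = if (method == "lasso") "l1" else "elastic_net",
                      lambda1 = cv$lambda1, lambda2 = cv$lambda2,
                      unpenalized = colnames(covs))
  nz <- names(fit$coefficients)[fit$coefficients != 0]
  intersect(nz, colnames(x))
}

#' Nested appearance-count groups
#'
#' Group g contains the SNPs selected in at least g of the CV folds, so the
#' groups are nested: group 5 (selected every time) is a subset of group 4,
#' and so on down to group 1 (selected at least once).
#'
#' @param counts A `stability_counts` from [cv_stability_select()].
#' @param n_groups Number of groups (defaults to the fold count).
#' @return A tibble with columns `group` and `rsids` (list-column).
#' @export
form_groups <- function(counts, n_groups = attr(counts, "k_folds") %||% 5) {
  tibble::tibble(
    group = seq_len(n_groups),
    rsids = purrr::map(seq_len(n_groups),
                       function(g) counts$rsid[counts$count >= g])
  )
}
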