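#' Stepwise logistic selection maximizing validation AUC
#'
#' Forward selection with backward pruning over candidate SNPs, keeping the
#' demographic covariates (sex, age, BMI) fixed in every model. Each step fits
#' logistic models on an inner training portion and evaluates AUC on a
#' held-out validation fifth of the supplied data; the move (addition, then
#' removal) with the largest AUC improvement is accepted while the gain
#' exceeds `tol`. Evaluating on an inner split rather than the test set avoids
#' the selection-on-test overfitting this workflow is designed to prevent.
#'
#' @param x Candidate SNP dosage matrix (training samples, imputed).
#' @param covs Covariate matrix (sex, age, bmi) for the same samples.
#' @param y Binary outcome.
#' @param tol Minimum AUC gain to accept a move (default 1e-4).
#' @param val_fraction Inner validation fraction (default 0.2).
#' @param max_steps Cap on the number of accepted additions.
#' @param seed Seed for the inner stratified split.
#' @return Character vector of selected SNP names, with attribute
#'   `auc_trajectory` (validation AUC after each accepted move).
#' @export
stepwise_auc_select <- function(x, covs, y, tol = 1e-4, val_fraction = 0.2,
                                max_steps = 30, seed = 1L) {
  x <- as_pred_matrix(x)
  if (ncol(x) == 0) return(structure(character(), auc_trajectory = numeric()))
  n <- length(y)
  k <- max(2L, round(1 / val_fraction))
  fold <- stratified_folds(y, k, derive_seed(seed, 41L))
  val <- fold == 1L
  if (length(unique(y[val])) < 2 || length(unique(y[!val])) < 2) {
    stop("inner split leaves a single-class side; more samples needed",
         call. = FALSE)
  }
  val_auc <- function(snps) {
    X <- cbind(`(Intercept)` = 1, covs, x[, snps, drop = FALSE])
    f <- tryCatch(
      suppressWarnings(stats::glm.fit(X[!val, , drop = FALSE], y[!val],
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    cf <- coef(f)
    cf[is.na(cf)] <- 0
    auc(drop(X[val, , drop = FALSE] %*% cf), y[val])$auc
  }
  selected <- character()
  current <- val_auc(selected)
  trajectory <- numeric()
  steps <- 0L
  repeat {
    cand <- setdiff(colnames(x), selected)
    if (length(cand) == 0 || steps >= max_steps) break
    gains <- vapply(cand, function(s) val_auc(c(selected, s)), numeric(1))
    best <- which.max(gains)
    if (length(best) == 0 || is.na(gains[best]) ||
        gains[best] - current <= tol) break
    selected <- c(selected, cand[best])
    current <- gains[best]
    trajectory <- c(trajectory, current)
    steps <- steps + 1L
    # backward pruning: drop any SNP whose removal improves validation AUC
    repeat {
      if (length(selected) <= 1) break
      drops <- vapply(selected,
                      function(s) val_auc(setdiff(selected, s)), numeric(1))
      bd <- which.max(drops)
      if (is.na(drops[bd]) || drops[bd] - current <= tol) break
      selected <- setdiff(selected, selected[bd])
      current <- drops[bd]
      trajectory <- c(trajectory, current)
    }
  }
  structure(selected, auc_trajectory = trajectory)
}
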