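#' Fit a (penalized) logistic regression
#'
#' Maximizes the binomial log-likelihood minus
#' \eqn{\lambda_1 \sum_j |\beta_j| + \lambda_2 \sum_j \beta_j^2}, with the
#' penalty applied only to predictors not listed in `unpenalized` (demographic
#' covariates such as sex/age/BMI are typically exempt). Penalized fits are
#' computed by glmnet; the (lambda1, lambda2) parameterization is mapped
#' exactly onto glmnet's (alpha, lambda), including its penalty-factor
#' rescaling, so the optimized objective is the one stated here. With
#' `standardize = TRUE` predictors are standardized internally and
#' coefficients returned on the original scale.
#'
#' @param x Numeric predictor matrix (or data frame) with column names.
#' @param y Binary outcome (0/1 or logical).
#' @param penalty One of `"none"`, `"l1"`, `"elastic_net"`.
#' @param lambda1 L1 penalty weight (>= 0).
#' @param lambda2 L2 penalty weight (>= 0, elastic net only).
#' @param unpenalized Character vector of column names exempt from the
#'   penalty.
#' @param standardize Standardize predictors internally before penalizing.
#' @return An object of class `psm_logit` with elements `intercept`,
#'   `coefficients` (named, original scale), `penalty`, `lambda1`, `lambda2`,
#'   `converged`, `separation`, `unpenalized`, `n`.
#' @export
fit_logistic <- function(x, y,
                         penalty = c("none", "l1", "elastic_net"),
                         lambda1 = 0, lambda2 = 0,
                         unpenalized = character(),
                         standardize = TRUE) {
  penalty <- match.arg(penalty)
  x <- as_pred_matrix(x)
  y <- as.integer(as.logical(y))
  assert_that(length(y) == nrow(x), "x and y dimensions disagree")
  if (all(y == y[1])) {
    stop("degenerate outcome: all responses identical", call. = FALSE)
  }
  assert_that(lambda1 >= 0 && lambda2 >= 0, "penalty weights must be >= 0")
  if (penalty == "none" || (lambda1 == 0 && lambda2 == 0)) {
    return(fit_logit_glm(x, y, penalty = "none", unpenalized = unpenalized))
  }
  n <- nrow(x)
  pf <- ifelse(colnames(x) %in% unpenalized, 0, 1)
  if (sum(pf) == 0) {
    return(fit_logit_glm(x, y, penalty = "none", unpenalized = unpenalized))
  }
  alpha <- if (penalty == "l1") 1 else lambda1 / (lambda1 + 2 * lambda2)
  if (penalty == "l1" && lambda2 > 0) {
    stop("lambda2 > 0 requires penalty = 'elastic_net'", call. = FALSE)
  }
  lambda_target <- (lambda1 + 2 * lambda2) / n
  # glmnet rescales penalty.factor to sum to nvars; compensate so the
  # effective per-variable penalty is exactly lambda_target.
  lambda_pass <- lambda_target * sum(pf) / ncol(x)
  path <- lambda_pass * c(64, 16, 4, 1)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = path, penalty.factor = pf,
                        standardize = standardize, thresh = 1e-12,
                        maxit = 1e6)
  cf <- as.numeric(coef(fit, s = lambda_pass, exact = FALSE))
  cf[-1][pf > 0 & abs(cf[-1]) < 1e-10] <- 0   # drop solver dust at the boundary
  structure(list(
    intercept = cf[1],
    coefficients = stats::setNames(cf[-1], colnames(x)),
    penalty = penalty, lambda1 = lambda1, lambda2 = lambda2, alpha = alpha,
    converged = TRUE, separation = FALSE,
    unpenalized = unpenalized, standardize = standardize, n = n
  ), class = "psm_logit")
}

# Unpenalized fit via IRLS; flags (quasi-)separation and caps runaway
# coefficients so downstream scoring stays finite.
fit_logit_glm <- function(x, y, penalty, unpenalized) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                   family = stats::binomial())
  )
  cf <- coef(fit)
  mu <- fit$fitted.values
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(cf[-1]) > 1e3)
  if (separation) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0 | !is.finite(sds)] <- 1
    cap <- 20 / sds
    cf[-1] <- pmin(pmax(cf[-1], -cap), cap)
  }
  structure(list(
    intercept = unname(cf[1]),
    coefficients = stats::setNames(unname(cf[-1]), colnames(x)),
    penalty = "none", lambda1 = 0, lambda2 = 0, alpha = NA_real_,
    converged = isTRUE(fit$converged) && !separation,
    separation = separation,
    unpenalized = unpenalized, standardize = FALSE, n = nrow(x)
  ), class = "psm_logit")
}

as_pred_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%d", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  assert_that(all(is.finite(x)), "predictor matrix must be finite")
  x
}

#' @export
predict.psm_logit <- function(object, newdata,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- as_pred_matrix(newdata)
  x <- x[, names(object$coefficients), drop = FALSE]
  eta <- object$intercept + drop(x %*% object$coefficients)
  if (type == "link") eta else inv_logit(eta)
}

#' @export
print.psm_logit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<psm_logit> penalty=%s lambda1=%.4g lambda2=%.4g | %d/%d nonzero, n=%d\n",
              x$penalty, x$lambda1, x$lambda2, nz,
              length(x$coefficients), x$n))
  invisible(x)
}

#' @export
tidy.psm_logit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    penalized = c(FALSE, !(names(x$coefficients) %in% x$unpenalized))
  )
}

#' @export
glance.psm_logit <- function(x, ...) {
  tibble::tibble(penalty = x$penalty, lambda1 = x$lambda1,
                 lambda2 = x$lambda2, n = x$n,
                 n_nonzero = sum(x$coefficients != 0),
                 converged = x$converged, separation = x$separation)
}

#' Select the L1 penalty by stratified k-fold cross-validation
#'
#' Evaluates a decreasing lambda grid (from the smallest lambda that zeroes
#' every penalized coefficient) by cross-validated binomial deviance with
#' folds stratified by outcome. `rule = "min"` returns the loss-minimizing
#' lambda (`lambda.min`); `rule = "one_se"` the largest lambda within one
#' standard error of that minimum (`lambda.1se`).
#'
#' @inheritParams fit_logistic
#' @param k_folds Number of CV folds (>= 2).
#' @param rule `"min"` or `"one_se"`.
#' @param alpha Elastic-net mixing weight (1 = LASSO).
#' @param seed Seed for the stratified fold assignment.
#' @return An object of class `psm_cv`: `lambda1`, `lambda2` (objective
#'   scale), `lambda_glmnet`, `alpha`, `rule`, and the CV path
#'   (`lambda_grid`, `cvm`, `cvsd`, `nzero`).
#' @export
cv_select_lambda <- function(x, y, k_folds = 5,
                             rule = c("min", "one_se"), alpha = 1,
                             unpenalized = character(),
                             standardize = TRUE, seed = 1L) {
  rule <- match.arg(rule)
  x <- as_pred_matrix(x)
  y <- as.integer(as.logical(y))
  assert_that(k_folds >= 2, "k_folds must be >= 2")
  if (min(table(y)) < k_folds) {
    stop("too few samples in the rarer class for stratified folds",
         call. = FALSE)
  }
  foldid <- stratified_folds(y, k_folds, seed)
  pf <- ifelse(colnames(x) %in% unpenalized, 0, 1)
  cv <- with_seed(derive_seed(seed, 11L), {
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                      foldid = foldid, penalty.factor = pf,
                      standardize = standardize,
                      type.measure = "deviance",
                      lambda.min.ratio = 0.001, nlambda = 100)
  })
  lam_g <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  lambda_target <- lam_g * ncol(x) / sum(pf)
  n <- nrow(x)
  structure(list(
    lambda1 = alpha * lambda_target * n,
    lambda2 = (1 - alpha) / 2 * lambda_target * n,
    lambda_glmnet = lam_g, alpha = alpha, rule = rule,
    lambda_grid = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
    nzero = as.integer(cv$nzero), k_folds = k_folds, seed = seed
  ), class = "psm_cv")
}

#' @export
print.psm_cv <- function(x, ...) {
  cat(sprintf("<psm_cv> rule=%s alpha=%.2f -> lambda1=%.4g lambda2=%.4g\n",
              x$rule, x$alpha, x$lambda1, x$lambda2))
  invisible(x)
}

# Fold ids stratified by class, seeded.
stratified_folds <- function(y, k, seed) {
  foldid <- integer(length(y))
  with_seed(derive_seed(seed, 10L), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  foldid
}

#' Serialize a fitted logistic model to JSON
#' @param fit A `psm_logit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  jsonlite::write_json(
    list(intercept = fit$intercept,
         coefficients = as.list(fit$coefficients),
         penalty = fit$penalty, lambda1 = fit$lambda1, lambda2 = fit$lambda2,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
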