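#' Single-SNP association scan
#'
#' Per-SNP logistic regression of case status on minor-allele dosage, with or
#' without adjustment for sex, age and BMI; the Wald p-value for the dosage
#' term is reported. Missing dosages are mean-imputed per SNP. SNPs that are
#' monomorphic in the analyzed samples are flagged and given p = 1.
#'
#' @param genotypes Samples-by-SNPs dosage matrix (rows aligned with
#'   `status`).
#' @param status Binary case indicator (or `"case"`/`"control"` character).
#' @param covariates Tibble/matrix with `sex`, `age`, `bmi` (required when
#'   `adjusted = TRUE`).
#' @param adjusted Adjust for the demographic covariates.
#' @return A tibble with columns `rsid`, `beta`, `se`, `p_value`,
#'   `monomorphic`, `adjusted`, `n`.
#' @export
single_snp_scan <- function(genotypes, status, covariates = NULL,
                            adjusted = TRUE) {
  y <- if (is.character(status)) as.integer(status == "case")
       else as.integer(as.logical(status))
  assert_that(length(y) == nrow(genotypes),
              "status length must match genotype rows")
  assert_that(!all(y == y[1]), "both classes must be present")
  covm <- NULL
  if (adjusted) {
    assert_that(!is.null(covariates), "adjusted scan needs covariates")
    covm <- as.matrix(as.data.frame(covariates)[, c("sex", "age", "bmi")])
  }
  n <- nrow(genotypes)
  out <- purrr::map(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    mu <- mean(g, na.rm = TRUE)
    if (is.nan(mu) || stats::var(g, na.rm = TRUE) %in% c(0, NA)) {
      return(tibble::tibble(beta = NA_real_, se = NA_real_, p_value = 1,
                            monomorphic = TRUE))
    }
    g[is.na(g)] <- mu
    X <- if (adjusted) cbind(1, g, covm) else cbind(1, g)
    w <- wald_dosage(X, y)
    tibble::tibble(beta = w$beta, se = w$se, p_value = w$p,
                   monomorphic = FALSE)
  })
  dplyr::bind_cols(
    tibble::tibble(rsid = colnames(genotypes) %||%
                     sprintf("snp%d", seq_len(ncol(genotypes)))),
    dplyr::bind_rows(out),
    tibble::tibble(adjusted = adjusted, n = n)
  )
}

# Wald statistic for column 2 (the dosage) of the design matrix, via the
# IRLS QR decomposition.
wald_dosage <- function(X, y) {
  f <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  p <- f$rank
  if (p < ncol(X)) {
    return(list(beta = NA_real_, se = NA_real_, p = 1))
  }
  R <- qr.R(f$qr)
  cov <- chol2inv(R)
  piv <- f$qr$pivot
  se <- sqrt(diag(cov))[order(piv)]
  beta <- unname(coef(f)[2])
  z <- beta / unname(se[2])
  list(beta = beta, se = unname(se[2]), p = 2 * stats::pnorm(-abs(z)))
}
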