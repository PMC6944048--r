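#' Train/test split, stratified and matched-pair aware
#'
#' Seeded random split taking `floor(train_fraction * n)` units. With
#' `stratified = TRUE` the floor is applied per status stratum so the case
#' fraction is preserved to within one sample (4,975 samples with 1,288 cases
#' at fraction 2/3 give 3,316 training samples of which 858 cases). When
#' `pairs` is supplied, matched pairs are the sampling unit and both members
#' land on the same side.
#'
#' @param cohort Tibble with `sample_id` and `status`.
#' @param train_fraction Fraction of units assigned to training (default 2/3).
#' @param seed Integer seed.
#' @param stratified Stratify by `status` (ignored when `pairs` is given).
#' @param pairs Optional `psm_pairs`; keeps pairs intact across the split.
#' @return A list with `train_ids` and `test_ids` (disjoint, exhaustive).
#' @export
train_test_split <- function(cohort, train_fraction = 2 / 3, seed = 1L,
                             stratified = TRUE, pairs = NULL) {
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  if (!is.null(pairs)) {
    n <- nrow(pairs)
    n_tr <- floor(train_fraction * n)
    tr <- with_seed(derive_seed(seed, 31L), sample(n, n_tr))
    train_ids <- c(pairs$case_id[tr], pairs$control_id[tr])
    test_ids <- c(pairs$case_id[-tr], pairs$control_id[-tr])
  } else if (stratified) {
    train_ids <- character()
    with_seed(derive_seed(seed, 31L), {
      for (st in unique(cohort$status)) {
        ids <- cohort$sample_id[cohort$status == st]
        train_ids <- c(train_ids,
                       sample(ids, floor(train_fraction * length(ids))))
      }
    })
    test_ids <- setdiff(cohort$sample_id, train_ids)
  } else {
    n <- nrow(cohort)
    tr <- with_seed(derive_seed(seed, 31L),
                    sample(n, floor(train_fraction * n)))
    train_ids <- cohort$sample_id[tr]
    test_ids <- cohort$sample_id[-tr]
  }
  if (length(train_ids) < 10 || length(test_ids) < 10) {
    stop("fewer than 10 samples on one side of the split", call. = FALSE)
  }
  list(train_ids = train_ids, test_ids = test_ids)
}

#' Assemble model inputs for a sample subset
#'
#' Extracts the dosage submatrix for a SNP set (missing calls imputed to the
#' training mean), the demographic covariate matrix and the binary outcome.
#'
#' @param genotypes Samples-by-SNPs dosage matrix.
#' @param cohort Tibble with `sample_id`, `sex`, `age`, `bmi`, `status`.
#' @param ids Sample IDs to extract.
#' @param rsids SNP columns to extract.
#' @param impute_means Optional named vector of per-SNP imputation means
#'   (supply the training means when building test data).
#' @return A list with `x` (SNP matrix), `covs` (matrix), `y` (0/1),
#'   `ids`, `impute_means`.
#' @export
model_frame <- function(genotypes, cohort, ids, rsids,
                        impute_means = NULL) {
  rows <- match(ids, rownames(genotypes))
  assert_that(!anyNA(rows), "ids missing from the genotype matrix")
  x <- genotypes[rows, rsids, drop = FALSE]
  if (is.null(impute_means)) {
    impute_means <- colMeans(x, na.rm = TRUE)
    impute_means[is.nan(impute_means)] <- 0
  }
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- impute_means[j]
  }
  crows <- match(ids, cohort$sample_id)
  covs <- as.matrix(cohort[crows, c("sex", "age", "bmi")])
  y <- as.integer(cohort$status[crows] == "case")
  list(x = x, covs = covs, y = y, ids = ids, impute_means = impute_means)
}
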