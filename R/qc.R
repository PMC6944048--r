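#' QC thresholds for genotype filtering
#'
#' Defaults are the standard GWAS quality-control cuts: HWE exact p >= 1e-6,
#' SNP call rate >= 95%, sample call rate >= 96%, MAF >= 0.05.
#'
#' @param hwe_p_min Minimum HWE exact-test p-value a SNP must reach.
#' @param snp_call_min Minimum per-SNP call rate.
#' @param sample_call_min Minimum per-sample call rate.
#' @param maf_min Minimum minor allele frequency.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-6, snp_call_min = 0.95,
                          sample_call_min = 0.96, maf_min = 0.05) {
  th <- list(hwe_p_min = hwe_p_min, snp_call_min = snp_call_min,
             sample_call_min = sample_call_min, maf_min = maf_min)
  ok <- vapply(th, function(x) is.numeric(x) && x > 0 && x <= 1, logical(1))
  assert_that(all(ok), "all QC thresholds must lie in (0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability (under the HWE null, where heterozygote counts follow
#' a hypergeometric-type distribution) of heterozygote counts no more probable
#' than the observed one. Heterozygote counts share the parity of the
#' minor-allele count.
#'
#' @param n_aa_hom,n_het,n_bb_hom Genotype counts: major homozygote,
#'   heterozygote, minor homozygote (label order is irrelevant).
#' @return A two-sided exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(70, 20, 10)
hwe_exact_test <- function(n_aa_hom, n_het, n_bb_hom) {
  counts <- c(n_aa_hom, n_het, n_bb_hom)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "genotype counts must be nonnegative integers")
  n <- sum(counts)
  assert_that(n >= 1, "all genotype counts are zero")
  r <- min(2 * n_aa_hom + n_het, 2 * n_bb_hom + n_het)  # minor allele count
  if (r == 0) return(1.0)
  hs <- seq(r %% 2, r, by = 2)
  hs <- hs[(n - (hs + (r - hs) / 2)) >= 0]
  # log P(h | n, r) up to the shared normalizing constant
  logp <- vapply(hs, function(h) {
    n_rr <- (r - h) / 2
    n_cc <- n - h - n_rr
    h * log(2) - lfactorial(h) - lfactorial(n_rr) - lfactorial(n_cc)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(hs == n_het)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-10)]))
}

#' Per-SNP call rate, minor allele frequency and HWE p-value
#'
#' @param genotypes Samples-by-SNPs dosage matrix (0/1/2/`NA`).
#' @return A tibble with columns `rsid`, `call_rate`, `maf`, `hwe_p` and the
#'   genotype counts `n_0`, `n_1`, `n_2`. SNPs with zero called genotypes get
#'   `call_rate = 0` and missing `maf`/`hwe_p`.
#' @export
snp_statistics <- function(genotypes) {
  assert_that(nrow(genotypes) >= 1, "genotype matrix has no samples")
  n <- nrow(genotypes)
  n0 <- colSums(genotypes == 0, na.rm = TRUE)
  n1 <- colSums(genotypes == 1, na.rm = TRUE)
  n2 <- colSums(genotypes == 2, na.rm = TRUE)
  ncalled <- n0 + n1 + n2
  p <- ifelse(ncalled > 0, (n1 + 2 * n2) / (2 * ncalled), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe_p <- rep(NA_real_, ncol(genotypes))
  idx <- which(ncalled > 0)
  hwe_p[idx] <- vapply(idx, function(j) hwe_exact_test(n0[j], n1[j], n2[j]),
                       numeric(1))
  tibble::tibble(
    rsid = colnames(genotypes) %||% sprintf("snp%d", seq_len(ncol(genotypes))),
    call_rate = unname(ncalled / n), maf = unname(maf), hwe_p = hwe_p,
    n_0 = as.integer(unname(n0)), n_1 = as.integer(unname(n1)),
    n_2 = as.integer(unname(n2))
  )
}

#' Apply quality-control filters to a genotype matrix
#'
#' Fixed order: (1) remove samples with call rate below
#' `thresholds$sample_call_min`; then, with SNP statistics recomputed on the
#' remaining samples, remove SNPs failing (2) the HWE test, (3) the SNP call
#' rate, (4) the MAF cut. The report itemizes removals per step.
#'
#' @param genotypes Samples-by-SNPs dosage matrix.
#' @param thresholds A [qc_thresholds()].
#' @return A list of class `qc_result`: `genotypes` (filtered matrix),
#'   `report` (tibble of per-step removal counts), `snp_stats` (statistics on
#'   the sample-filtered matrix).
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n_in <- dim(genotypes)
  sample_cr <- rowMeans(!is.na(genotypes))
  if (ncol(genotypes) == 0) sample_cr <- rep(1, nrow(genotypes))
  keep_s <- sample_cr >= thresholds$sample_call_min
  g <- genotypes[keep_s, , drop = FALSE]
  st <- if (nrow(g) > 0 && ncol(g) > 0) snp_statistics(g) else NULL
  if (!is.null(st)) {
    fail_hwe <- !is.na(st$hwe_p) & st$hwe_p < thresholds$hwe_p_min
    fail_cr <- !fail_hwe & st$call_rate < thresholds$snp_call_min
    fail_maf <- !fail_hwe & !fail_cr &
      (is.na(st$maf) | st$maf < thresholds$maf_min)
    keep_v <- !(fail_hwe | fail_cr | fail_maf)
  } else {
    fail_hwe <- fail_cr <- fail_maf <- logical(ncol(g))
    keep_v <- rep(TRUE, ncol(g))
  }
  out <- g[, keep_v, drop = FALSE]
  info <- attr(genotypes, "snp_info")
  if (!is.null(info)) attr(out, "snp_info") <- info[keep_v, , drop = FALSE]
  if (nrow(out) == 0 || ncol(out) == 0) {
    warning("QC removed every sample or SNP; returning an empty matrix",
            call. = FALSE)
  }
  report <- tibble::tibble(
    step = c("sample_call_rate", "snp_hwe", "snp_call_rate", "snp_maf"),
    dimension = c("samples", "snps", "snps", "snps"),
    removed = c(sum(!keep_s), sum(fail_hwe), sum(fail_cr), sum(fail_maf))
  )
  structure(list(genotypes = out, report = report, snp_stats = st,
                 n_in = n_in, n_out = dim(out)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d x %d -> %d x %d\n",
              x$n_in[1], x$n_in[2], x$n_out[1], x$n_out[2]))
  print(x$report)
  invisible(x)
}

#' Classify a subject as T2D case, control, or excluded
#'
#' Diagnostic criteria: a subject is a **case** if any of fasting plasma
#' glucose >= 126 mg/dL, HbA1c >= 6.5%, 2-h postprandial glucose >= 200
#' mg/dL, or treated diabetes with onset age >= 40 years. A subject is a
#' **control** if every available measurement is normal (fpg <= 100,
#' hba1c < 5.7, pg2h <= 140) and there is no diabetes history. Everyone else
#' (intermediate values, treated diabetes with early/unknown onset) is
#' **excluded**.
#'
#' @param fpg Fasting plasma glucose (mg/dL) or `NA`.
#' @param hba1c Glycated hemoglobin (%) or `NA`.
#' @param pg2h 2-hour postprandial glucose (mg/dL) or `NA`.
#' @param dm_history Diabetes history / treatment flag (0/1 or logical).
#' @param onset_age Age of disease onset (years) or `NA`.
#' @return Character vector in `c("case", "control", "excluded")`
#'   (vectorized over the inputs).
#' @export
#' @examples
#' classify_t2d(fpg = 130)                      # case
#' classify_t2d(fpg = 95, hba1c = 5.2, pg2h = 120, dm_history = 0)  # control
#' classify_t2d(fpg = 110, hba1c = 6.0, dm_history = 0)             # excluded
classify_t2d <- function(fpg = NA_real_, hba1c = NA_real_, pg2h = NA_real_,
                         dm_history = NA, onset_age = NA_real_) {
  n <- max(length(fpg), length(hba1c), length(pg2h), length(dm_history),
           length(onset_age))
  fpg <- rep_len(as.numeric(fpg), n)
  hba1c <- rep_len(as.numeric(hba1c), n)
  pg2h <- rep_len(as.numeric(pg2h), n)
  dm_history <- rep_len(as.logical(dm_history), n)
  onset_age <- rep_len(as.numeric(onset_age), n)
  usable <- !is.na(fpg) | !is.na(hba1c) | !is.na(pg2h) | !is.na(dm_history)
  if (any(!usable)) {
    stop("no usable clinical fields for at least one record", call. = FALSE)
  }
  any_neg <- function(x) any(x < 0, na.rm = TRUE)
  if (any_neg(fpg) || any_neg(hba1c) || any_neg(pg2h) || any_neg(onset_age)) {
    stop("clinical measurements must be nonnegative", call. = FALSE)
  }
  is_case <- (!is.na(fpg) & fpg >= 126) |
    (!is.na(hba1c) & hba1c >= 6.5) |
    (!is.na(pg2h) & pg2h >= 200) |
    (!is.na(dm_history) & dm_history & !is.na(onset_age) & onset_age >= 40)
  ok <- function(x, cond) is.na(x) | cond
  is_control <- ok(fpg, fpg <= 100) & ok(hba1c, hba1c < 5.7) &
    ok(pg2h, pg2h <= 140) &
    (is.na(dm_history) | !dm_history)
  dplyr::case_when(is_case ~ "case", is_control ~ "control",
                   TRUE ~ "excluded")
}
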