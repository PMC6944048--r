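test_that("HWE exact test matches enumeration and its symmetries", {
  # worked example: counts (3, 5, 2), minor-allele count 9
  expect_equal(hwe_exact_test(3, 5, 2), oracle_hwe(3, 5, 2),
               tolerance = 1e-12)
  # monomorphic: single attainable configuration
  expect_identical(hwe_exact_test(25, 0, 0), 1.0)
  # allele-label symmetry
  for (tr in list(c(10, 4, 1), c(2, 9, 7), c(0, 6, 14))) {
    expect_equal(hwe_exact_test(tr[1], tr[2], tr[3]),
                 hwe_exact_test(tr[3], tr[2], tr[1]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("HWE exact test agrees with enumeration over small triples", {
  # spot-check grid here; the exhaustive sweep to N = 50 runs in acceptance
  for (n in c(5, 11, 20)) {
    for (n_aa in 0:n) {
      for (n_ab in 0:(n - n_aa)) {
        n_bb <- n - n_aa - n_ab
        expect_equal(hwe_exact_test(n_aa, n_ab, n_bb),
                     oracle_hwe(n_aa, n_ab, n_bb), tolerance = 1e-12)
      }
    }
  }
})

test_that("snp_statistics computes call rate, MAF and handles edge cases", {
  g <- cbind(
    s1 = c(rep(0, 70), rep(1, 20), rep(2, 10)),        # maf 0.2
    s2 = c(rep(1, 100)),                               # all het: maf 0.5
    s3 = c(rep(NA, 6), rep(0, 94)),                    # call rate 0.94
    s4 = rep(NA_real_, 100)                            # nothing called
  )
  st <- snp_statistics(g)
  expect_equal(st$maf[1], 0.2)
  expect_equal(st$maf[2], 0.5)
  expect_equal(st$call_rate[3], 0.94)
  expect_equal(st$call_rate[4], 0)
  expect_true(is.na(st$maf[4]) && is.na(st$hwe_p[4]))
})

test_that("apply_qc removes exactly the failing SNPs, in order, idempotently", {
  psmsnp:::with_seed(7, {
    g <- vapply(rep(0.3, 30), function(p) rbinom(40, 2, p), numeric(40))
    colnames(g) <- paste0("s", 1:30)
    rownames(g) <- paste0("i", 1:40)
  })
  g[1:8, 2] <- NA           # SNP s2: call rate 0.8 < 0.95
  g[, 3] <- c(1, rep(0, 39))  # SNP s3: maf 1/80 < 0.05
  res <- apply_qc(g)
  expect_setequal(colnames(res$genotypes), paste0("s", setdiff(1:30, 2:3)))
  expect_equal(res$report$removed[res$report$step == "snp_call_rate"], 1)
  expect_equal(res$report$removed[res$report$step == "snp_maf"], 1)
  # removals account for the dimension change
  expect_equal(sum(res$report$removed[res$report$dimension == "snps"]),
               ncol(g) - ncol(res$genotypes))
  # idempotence
  res2 <- apply_qc(res$genotypes)
  expect_identical(res2$genotypes, res$genotypes)
  expect_equal(sum(res2$report$removed), 0)
})

test_that("apply_qc removes low-call-rate samples and HWE failures", {
  psmsnp:::with_seed(8, {
    g <- vapply(rep(0.4, 10), function(p) rbinom(50, 2, p), numeric(50))
    colnames(g) <- paste0("s", 1:10)
    rownames(g) <- paste0("i", 1:50)
  })
  g[1, 1:5] <- NA                 # sample i1: call rate 0.5 < 0.96
  g[-1, 10] <- rep(c(0, 2), length.out = 49)  # gross heterozygote deficit
  expect_lt(hwe_exact_test(25, 0, 24), 1e-6)
  res <- apply_qc(g)
  expect_false("i1" %in% rownames(res$genotypes))
  expect_false("s10" %in% colnames(res$genotypes))
  expect_equal(res$report$removed[res$report$step == "sample_call_rate"], 1)
  expect_equal(res$report$removed[res$report$step == "snp_hwe"], 1)
})

test_that("classify_t2d applies the diagnostic criteria", {
  expect_equal(classify_t2d(fpg = 130), "case")
  expect_equal(classify_t2d(hba1c = 6.5), "case")
  expect_equal(classify_t2d(pg2h = 200), "case")
  expect_equal(classify_t2d(fpg = 95, dm_history = 1, onset_age = 45), "case")
  expect_equal(classify_t2d(fpg = 95, hba1c = 5.2, pg2h = 120,
                            dm_history = 0), "control")
  expect_equal(classify_t2d(fpg = 110, hba1c = 6.0, dm_history = 0),
               "excluded")
  # treated diabetes without onset age >= 40 is excluded, not case
  expect_equal(classify_t2d(fpg = 95, dm_history = 1), "excluded")
  expect_equal(classify_t2d(fpg = 95, dm_history = 1, onset_age = 30),
               "excluded")
  # partial information: a single normal measurement with no history
  expect_equal(classify_t2d(fpg = 90), "control")
  expect_error(classify_t2d(), "usable")
  expect_error(classify_t2d(fpg = -5), "nonnegative")
})

test_that("classification partitions a synthetic cohort into three classes", {
  ch <- small_cohort()
  cls <- classify_t2d(fpg = ch$cohort$fpg, hba1c = ch$cohort$hba1c,
                      pg2h = ch$cohort$pg2h,
                      dm_history = ch$cohort$dm_history,
                      onset_age = ch$cohort$onset_age)
  expect_true(all(cls %in% c("case", "control", "excluded")))
  expect_gt(sum(cls == "excluded"), 0)
  expect_gt(sum(cls == "case"), 0)
  expect_gt(sum(cls == "control"), 0)
})

test_that("simulated SNPs rarely fail the HWE filter", {
  cfg <- sim_config(n_samples = 500, n_snps = 1000, missing_rate = 0,
                    seed = 55)
  st <- snp_statistics(simulate_genotypes(cfg))
  expect_lt(mean(st$hwe_p < 0.01), 0.025)
})
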