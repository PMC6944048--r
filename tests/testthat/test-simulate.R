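test_that("config validation rejects contradictory settings", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(n_snps = 10, n_direct_causal = 8,
                          n_bmi_causal = 8), "causal")
  expect_error(sim_config(h2_bmi = 1), "h2_bmi")
  expect_error(sim_config(h2_bmi = 0, b_bmi = 0.5), "contradicts")
  expect_error(sim_config(h2_bmi = 0.4, n_bmi_causal = 0), "n_bmi_causal")
})

test_that("genotypes follow HWE at their drawn allele frequencies", {
  # fixed MAF 0.3: expected genotype frequencies (0.49, 0.42, 0.09)
  cfg <- sim_config(n_samples = 10000, n_snps = 1, maf_range = c(0.3, 0.3),
                    n_direct_causal = 0, n_bmi_causal = 1, h2_bmi = 0.4,
                    missing_rate = 0, seed = 11)
  g <- simulate_genotypes(cfg)
  counts <- table(factor(g[, 1], levels = 0:2))
  expected <- c(0.49, 0.42, 0.09)
  for (k in 1:3) {
    ci <- qbinom(c(0.005, 0.995), 10000, expected[k])
    expect_gte(counts[k], ci[1])
    expect_lte(counts[k], ci[2])
  }

  # p = 0.5: mean dosage 1 by symmetry
  cfg2 <- sim_config(n_samples = 5000, n_snps = 4, maf_range = c(0.5, 0.5),
                     n_direct_causal = 0, n_bmi_causal = 1, h2_bmi = 0.4,
                     missing_rate = 0, seed = 12)
  g2 <- simulate_genotypes(cfg2)
  se <- sqrt(0.5 / 5000)   # var of Binomial(2, .5) is 0.5
  expect_true(all(abs(colMeans(g2) - 1) < 3 * se))

  # missing_rate = 0 leaves no NA
  expect_false(anyNA(g2))
})

test_that("MAF spectrum is uniform on maf_range and mask obeys missing_rate", {
  cfg <- sim_config(n_samples = 50, n_snps = 1000, missing_rate = 0.02,
                    seed = 13)
  g <- simulate_genotypes(cfg)
  mafs <- snp_info(g)$maf_true
  ks <- suppressWarnings(ks.test(mafs, "punif", 0.05, 0.5))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(is.na(g)), 0.01)
  expect_lt(mean(is.na(g)), 0.03)
})

test_that("BMI heritability and demographic distributions are reproduced", {
  cfg <- sim_config(n_samples = 20000, n_snps = 50, n_direct_causal = 0,
                    n_bmi_causal = 20, h2_bmi = 0.4, missing_rate = 0,
                    seed = 21)
  g <- simulate_genotypes(cfg)
  causal <- psmsnp:::pick_causal(cfg, colnames(g))$bmi_causal
  cov <- simulate_covariates(g, cfg, causal)

  # variance-decomposition oracle: R^2 of BMI on the true causal dosages
  r2 <- summary(lm(cov$bmi ~ g[, causal]))$r.squared
  expect_gt(r2, 0.37)
  expect_lt(r2, 0.43)

  # age matches its configured 51.44 +/- 8.85 within 3 SE
  expect_lt(abs(mean(cov$age) - 51.44), 3 * 8.85 / sqrt(20000))
  expect_lt(abs(sd(cov$age) - 8.85), 3 * 8.85 / sqrt(2 * 20000))

  # h2 = 0: BMI uncorrelated with dosages
  cfg0 <- sim_config(n_samples = 5000, n_snps = 20, n_direct_causal = 0,
                     n_bmi_causal = 0, h2_bmi = 0, missing_rate = 0,
                     seed = 22)
  g0 <- simulate_genotypes(cfg0)
  cov0 <- simulate_covariates(g0, cfg0, character())
  cors <- abs(cor(cov0$bmi, g0))
  expect_true(all(cors < 4 / sqrt(5000)))
})

test_that("disease model hits its intercept-implied prevalence and effects", {
  # intercept = logit(0.26), all effects zero -> case fraction ~ 0.26
  cfg <- sim_config(n_samples = 10000, n_snps = 5, n_direct_causal = 0,
                    n_bmi_causal = 1, beta_direct = 0,
                    gamma_demo = c(0, 0, 0), intercept = psmsnp::logit(0.26),
                    missing_rate = 0, seed = 31)
  g <- simulate_genotypes(cfg)
  cov <- simulate_covariates(g, cfg, colnames(g)[1])
  dis <- simulate_disease(g, cov, cfg, character())
  ci <- qbinom(c(0.005, 0.995), 10000, 0.26) / 10000
  expect_gt(mean(dis$case), ci[1])
  expect_lt(mean(dis$case), ci[2])

  # all effects and intercept zero -> prevalence 1/2
  cfg2 <- sim_config(n_samples = 4000, n_snps = 5, n_direct_causal = 0,
                     n_bmi_causal = 1, beta_direct = 0,
                     gamma_demo = c(0, 0, 0), intercept = 0,
                     missing_rate = 0, seed = 32)
  g2 <- simulate_genotypes(cfg2)
  cov2 <- simulate_covariates(g2, cfg2, colnames(g2)[1])
  dis2 <- simulate_disease(g2, cov2, cfg2, character())
  expect_lt(abs(mean(dis2$case) - 0.5), 3 * sqrt(0.25 / 4000))

  # a strong single causal SNP raises case dosage above control dosage
  cfg3 <- sim_config(n_samples = 3000, n_snps = 5, n_direct_causal = 1,
                     n_bmi_causal = 1, beta_direct = 2,
                     gamma_demo = c(0, 0, 0), intercept = -1,
                     missing_rate = 0, seed = 33)
  g3 <- simulate_genotypes(cfg3)
  causal3 <- psmsnp:::pick_causal(cfg3, colnames(g3))
  cov3 <- simulate_covariates(g3, cfg3, causal3$bmi_causal)
  dis3 <- simulate_disease(g3, cov3, cfg3, causal3$direct_causal)
  dos <- g3[, causal3$direct_causal]
  expect_gt(mean(dos[dis3$case]), mean(dos[!dis3$case]))
})

test_that("cohorts are reproducible and internally consistent", {
  cfg <- sim_config(n_samples = 300, n_snps = 30, n_direct_causal = 3,
                    n_bmi_causal = 3, seed = 41)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)

  expect_true(all(a$truth$direct_causal %in% colnames(a$genotypes)))
  expect_true(all(a$truth$bmi_causal %in% colnames(a$genotypes)))
  expect_length(intersect(a$truth$direct_causal, a$truth$bmi_causal), 0)

  # clinical fields reproduce the status labels under the diagnostic rules
  cls <- classify_t2d(fpg = a$cohort$fpg, hba1c = a$cohort$hba1c,
                      pg2h = a$cohort$pg2h, dm_history = a$cohort$dm_history,
                      onset_age = a$cohort$onset_age)
  expect_identical(cls, a$cohort$status)
  expect_true(all(c("case", "control", "excluded") %in% a$cohort$status))
})

test_that("adjusting for BMI attenuates BMI-mediated SNP signals", {
  zs <- purrr::map_dfr(1:4, function(s) {
    ch <- simulate_cohort(sim_config(
      n_samples = 1500, n_snps = 40, n_direct_causal = 0, n_bmi_causal = 10,
      h2_bmi = 0.5, gamma_demo = c(0, 0, 0.3), missing_rate = 0,
      seed = 500 + s
    ))
    coh <- analyzed_cohort(ch)
    g <- ch$genotypes[coh$sample_id, ch$truth$bmi_causal]
    adj <- single_snp_scan(g, coh$status, coh[, c("sex", "age", "bmi")],
                           adjusted = TRUE)
    raw <- single_snp_scan(g, coh$status, adjusted = FALSE)
    tibble::tibble(z_adj = mean(abs(adj$beta / adj$se), na.rm = TRUE),
                   z_raw = mean(abs(raw$beta / raw$se), na.rm = TRUE))
  })
  # conditioning on the mediator shrinks the mean |z| of BMI-causal SNPs
  expect_lt(mean(zs$z_adj), mean(zs$z_raw))
})
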