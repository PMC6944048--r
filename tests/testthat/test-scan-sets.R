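test_that("association scan is calibrated under the null and powered", {
  # null: dosages independent of status -> uniform p-values
  psmsnp:::with_seed(61, {
    g <- vapply(runif(300, 0.1, 0.5), function(p) rbinom(400, 2, p),
                numeric(400))
    colnames(g) <- sprintf("rs%03d", seq_len(ncol(g)))
    y <- rbinom(400, 1, 0.3)
  })
  res <- single_snp_scan(g, y, adjusted = FALSE)
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)

  # power: a planted strong SNP ranks first
  hits <- vapply(1:10, function(s) {
    psmsnp:::with_seed(70 + s, {
      gp <- vapply(runif(50, 0.2, 0.4), function(p) rbinom(300, 2, p),
                   numeric(300))
      colnames(gp) <- sprintf("rs%03d", 1:50)
      yp <- rbinom(300, 1, 1 / (1 + exp(1 - 1.2 * gp[, 25])))
    })
    resp <- single_snp_scan(gp, yp, adjusted = FALSE)
    resp$rsid[which.min(resp$p_value)] == "rs025"
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # monomorphic SNPs are flagged with p = 1
  g[, 1] <- 0
  res2 <- single_snp_scan(g, y, adjusted = FALSE)
  expect_true(res2$monomorphic[1])
  expect_equal(res2$p_value[1], 1)
})

scan_fixture <- function() {
  # deterministic scan results with known p ordering
  tibble::tibble(
    rsid = sprintf("rs%02d", 1:10),
    beta = 0.1, se = 0.1,
    p_value = c(0.01, 0.20, 0.03, 0.5, 0.05, 0.9, 0.02, 0.4, 0.03, 0.7),
    monomorphic = FALSE, adjusted = TRUE, n = 100
  )
}

test_that("top-k set takes the smallest p-values with the rsid tie rule", {
  res <- scan_fixture()
  s <- build_kare_set(res, 3)
  expect_equal(s$rsids, c("rs01", "rs07", "rs03"))   # 0.01, 0.02, 0.03(tie->rs03)
  # tie at the boundary: rs03 and rs09 share p = 0.03; rs03 enters first
  s4 <- build_kare_set(res, 4)
  expect_equal(s4$rsids[4], "rs09")
  expect_warning(sall <- build_kare_set(res, 99), "available")
  expect_equal(length(sall$rsids), 10)
})

test_that("catalog set puts genotyped catalog SNPs first and fills by p", {
  res <- scan_fixture()
  s <- build_gwas_kare_set(c("rs04", "rs06", "rsX1"), res, 5)
  # rsX1 is not genotyped -> excluded; catalog members first, then top p
  expect_equal(sort(s$rsids[1:2]), c("rs04", "rs06"))
  expect_equal(s$rsids[3:5], c("rs01", "rs07", "rs03"))
  # empty catalog degenerates to the data-driven set
  s0 <- build_gwas_kare_set(character(), res, 3)
  expect_equal(s0$rsids, build_kare_set(res, 3)$rsids)
  # overlap larger than k keeps the best catalog SNPs
  expect_warning(s1 <- build_gwas_kare_set(res$rsid, res, 2), "overlap")
  expect_equal(s1$rsids, c("rs01", "rs07"))
})

test_that("gene-restricted set draws only from catalog genes", {
  res <- scan_fixture()
  ann <- tibble::tibble(rsid = res$rsid,
                        gene = rep(c("G1", "G2", "G3", "G4", "G5"), each = 2))
  s <- build_catagene_set(ann, c("G1", "G4"), res, 3)
  # pool: rs01 rs02 (G1), rs07 rs08 (G4); top 3 by p
  expect_equal(s$rsids, c("rs01", "rs07", "rs02"))
  # absent catalog gene contributes nothing
  expect_warning(s0 <- build_catagene_set(ann, "NOPE", res, 3), "no genotyped")
  expect_equal(length(s0$rsids), 0)
  # all SNPs in catalog genes degenerates to the data-driven set
  sall <- build_catagene_set(ann, unique(ann$gene), res, 4)
  expect_equal(sall$rsids, build_kare_set(res, 4)$rsids)
})

test_that("catalog and annotation files round-trip through their readers", {
  cat_path <- tempfile()
  writeLines(c("# catalog", "rs01", "", "rs02"), cat_path)
  expect_equal(read_snp_catalog(cat_path), c("rs01", "rs02"))
  ann_path <- tempfile()
  readr::write_tsv(tibble::tibble(rsid = c("rs01", "rs02"),
                                  chrom = c("1", "2"),
                                  gene = c("G1", "G2")), ann_path)
  ann <- read_snp_annotation(ann_path)
  expect_equal(ann$gene, c("G1", "G2"))
})

test_that("causal SNPs are increasingly captured as effects grow", {
  frac_captured <- function(beta, s) {
    ch <- simulate_cohort(sim_config(
      n_samples = 800, n_snps = 120, n_direct_causal = 8, n_bmi_causal = 4,
      beta_direct = beta, missing_rate = 0, seed = 9000 + s
    ))
    coh <- analyzed_cohort(ch)
    g <- ch$genotypes[coh$sample_id, ]
    res <- single_snp_scan(g, coh$status, coh[, c("sex", "age", "bmi")])
    top <- build_kare_set(res, 20)$rsids
    mean(ch$truth$direct_causal %in% top)
  }
  grid <- tidyr::expand_grid(beta = c(0, 0.35, 0.9), s = 1:5)
  cap <- purrr::pmap_dbl(grid, frac_captured)
  m <- tapply(cap, grid$beta, mean)
  expect_lt(m[["0"]], m[["0.35"]])
  expect_lt(m[["0.35"]], m[["0.9"]])
})
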