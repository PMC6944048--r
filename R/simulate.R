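#' Simulate an additive-coded genotype matrix in Hardy-Weinberg equilibrium
#'
#' Each SNP is assigned a minor allele frequency drawn uniformly from
#' `config$maf_range`; genotype dosages (0, 1, 2 minor alleles) are drawn
#' independently with HWE probabilities \eqn{((1-p)^2, 2p(1-p), p^2)}, i.e.
#' Binomial(2, p). Calls are masked missing (`NA`) independently at
#' `config$missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A numeric samples-by-SNPs matrix with sample IDs as rownames and
#'   rsIDs as colnames. Attribute `snp_info` holds a tibble with columns
#'   `rsid`, `maf_true`, `gene` (a synthetic gene map, `snps_per_gene` SNPs
#'   per gene).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  n <- config$n_samples
  m <- config$n_snps
  with_seed(derive_seed(config$seed, 1L), {
    mafs <- runif(m, config$maf_range[1], config$maf_range[2])
    g <- vapply(seq_len(m), function(j) rbinom(n, 2L, mafs[j]),
                numeric(n))
    g <- matrix(as.numeric(g), nrow = n, ncol = m)
    if (config$missing_rate > 0 && m > 0) {
      g[runif(n * m) < config$missing_rate] <- NA_real_
    }
    rownames(g) <- sprintf("S%05d", seq_len(n))
    colnames(g) <- sprintf("rs%06d", seq_len(m))
    genes <- if (m > 0) {
      sprintf("GENE%04d", ceiling(seq_len(m) / config$snps_per_gene))
    } else character()
    attr(g, "snp_info") <- tibble::tibble(
      rsid = colnames(g) %||% character(),
      maf_true = mafs,
      gene = genes
    )
    g
  })
}

#' SNP metadata attached to a simulated genotype matrix
#' @param genotypes A matrix from [simulate_genotypes()].
#' @return A tibble with columns `rsid`, `maf_true`, `gene`.
#' @export
snp_info <- function(genotypes) {
  info <- attr(genotypes, "snp_info")
  if (is.null(info)) {
    info <- tibble::tibble(rsid = colnames(genotypes),
                           maf_true = NA_real_, gene = NA_character_)
  }
  info
}

# Dosages centered at 2p with missing values imputed to the mean (0 after
# centering); used only inside the generator.
centered_dosage <- function(genotypes, rsids, p) {
  gc <- genotypes[, rsids, drop = FALSE]
  gc <- sweep(gc, 2, 2 * p)
  gc[is.na(gc)] <- 0
  gc
}

#' Simulate demographic covariates with a heritable BMI component
#'
#' Sex is Bernoulli, age Normal, and BMI is the sum of a population mean, a
#' genetic term \eqn{\sum_k b (g_{ik} - 2 p_k)} over the BMI-causal SNPs, and
#' Normal environmental noise scaled so the genetic fraction of BMI variance
#' equals `config$h2_bmi`. This is the heritable-confounder mechanism by which
#' unmatched case-control comparisons underestimate the SNP contribution.
#'
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @param bmi_causal Character vector of BMI-causal rsIDs; default takes a
#'   seeded sample of `config$n_bmi_causal` SNPs.
#' @return A tibble with columns `sample_id`, `sex`, `age`, `bmi`.
#' @export
simulate_covariates <- function(genotypes, config, bmi_causal = NULL) {
  validate_sim_config(config)
  n <- nrow(genotypes)
  info <- snp_info(genotypes)
  if (is.null(bmi_causal)) {
    bmi_causal <- pick_causal(config, colnames(genotypes))$bmi_causal
  }
  with_seed(derive_seed(config$seed, 2L), {
    sex <- rbinom(n, 1L, config$sex_prob)
    age <- rnorm(n, config$age_mean_sd[1], config$age_mean_sd[2])
    mu_bmi <- config$bmi_mean_sd[1]
    sd_bmi <- config$bmi_mean_sd[2]
    if (config$h2_bmi > 0 && length(bmi_causal) > 0) {
      p <- info$maf_true[match(bmi_causal, info$rsid)]
      vg_unit <- sum(2 * p * (1 - p))   # genetic variance per unit b^2
      if (is.na(config$b_bmi)) {
        # derive b so Var_gen = h2 * sd_bmi^2 and total SD stays sd_bmi
        b <- sqrt(config$h2_bmi * sd_bmi^2 / vg_unit)
        var_e <- (1 - config$h2_bmi) * sd_bmi^2
      } else {
        b <- config$b_bmi
        var_gen <- b^2 * vg_unit
        var_e <- var_gen * (1 - config$h2_bmi) / config$h2_bmi
      }
      gterm <- drop(centered_dosage(genotypes, bmi_causal, p) %*%
                      rep(b, length(bmi_causal)))
      bmi <- mu_bmi + gterm + rnorm(n, 0, sqrt(var_e))
    } else {
      bmi <- rnorm(n, mu_bmi, sd_bmi)
    }
    tibble::tibble(sample_id = rownames(genotypes),
                   sex = as.integer(sex), age = age, bmi = bmi)
  })
}

#' Simulate disease status under a logistic model
#'
#' The case probability is
#' \eqn{\mathrm{logit}^{-1}(\beta_0 + \sum_k \beta g_{ik} + \gamma_1 sex_i +
#' \gamma_2 age_i + \gamma_3 BMI_i)} where the sum runs over the
#' direct-causal SNPs only; BMI-causal SNPs influence disease exclusively
#' through the BMI covariate. If `config$intercept` is `NA` it is calibrated
#' so the mean case probability equals `config$prevalence`.
#'
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param covariates Tibble from [simulate_covariates()].
#' @param config A [sim_config()].
#' @param direct_causal Character vector of direct-causal rsIDs; default takes
#'   a seeded sample disjoint from the BMI-causal set.
#' @return `covariates` with an added logical `case` column.
#' @export
simulate_disease <- function(genotypes, covariates, config,
                             direct_causal = NULL) {
  validate_sim_config(config)
  if (is.null(direct_causal)) {
    direct_causal <- pick_causal(config, colnames(genotypes))$direct_causal
  }
  info <- snp_info(genotypes)
  lp <- config$gamma_demo["sex"] * covariates$sex +
    config$gamma_demo["age"] * covariates$age +
    config$gamma_demo["bmi"] * covariates$bmi
  if (length(direct_causal) > 0 && config$beta_direct != 0) {
    p <- info$maf_true[match(direct_causal, info$rsid)]
    g <- genotypes[, direct_causal, drop = FALSE]
    for (j in seq_along(direct_causal)) {           # mean-impute missing
      g[is.na(g[, j]), j] <- 2 * p[j]
    }
    lp <- lp + drop(g %*% rep(config$beta_direct, length(direct_causal)))
  }
  b0 <- config$intercept
  if (is.na(b0)) {
    b0 <- stats::uniroot(
      function(c0) mean(inv_logit(c0 + lp)) - config$prevalence,
      interval = c(-60, 60), tol = 1e-10
    )$root
  }
  with_seed(derive_seed(config$seed, 3L), {
    case <- rbinom(length(lp), 1L, inv_logit(b0 + lp)) == 1L
    dplyr::mutate(covariates, case = case)
  })
}

# Seeded, disjoint draws of the direct-causal and BMI-causal SNP index sets.
pick_causal <- function(config, rsids) {
  with_seed(derive_seed(config$seed, 4L), {
    k <- config$n_direct_causal + config$n_bmi_causal
    picked <- if (k > 0) sample(rsids, k) else character()
    list(
      direct_causal = picked[seq_len(config$n_direct_causal)],
      bmi_causal = picked[config$n_direct_causal + seq_len(config$n_bmi_causal)]
    )
  })
}

# Clinical fields drawn conditional on simulated status so that Table-1 style
# classification reproduces it: cases diagnostic on all three glucose
# criteria, controls normal, and an intermediate "prediabetic" stratum that
# classifies as excluded.
simulate_clinical <- function(case, config) {
  n <- length(case)
  with_seed(derive_seed(config$seed, 5L), {
    grp <- ifelse(case, "case",
                  ifelse(runif(n) < config$intermediate_rate,
                         "intermediate", "control"))
    fpg <- hba1c <- pg2h <- numeric(n)
    i <- grp == "case"
    fpg[i] <- 126 + stats::rgamma(sum(i), shape = 2, scale = 12)
    hba1c[i] <- 6.5 + stats::rgamma(sum(i), shape = 2, scale = 0.5)
    pg2h[i] <- 200 + stats::rgamma(sum(i), shape = 2, scale = 25)
    i <- grp == "intermediate"
    fpg[i] <- runif(sum(i), 101, 125)
    hba1c[i] <- runif(sum(i), 5.7, 6.4)
    pg2h[i] <- runif(sum(i), 141, 199)
    i <- grp == "control"
    fpg[i] <- runif(sum(i), 80, 100)
    hba1c[i] <- runif(sum(i), 4.8, 5.6)
    pg2h[i] <- runif(sum(i), 90, 140)
    dm_history <- as.integer(case & runif(n) < 0.3)
    onset_age <- ifelse(dm_history == 1, round(runif(n, 40, 60)), NA_real_)
    tibble::tibble(fpg = round(fpg, 1), hba1c = round(hba1c, 2),
                   pg2h = round(pg2h, 1), dm_history = dm_history,
                   onset_age = onset_age)
  })
}

#' Generate a complete synthetic case-control cohort
#'
#' Runs [simulate_genotypes()], [simulate_covariates()] and
#' [simulate_disease()] under one seed, adds clinical glucose fields
#' consistent with the simulated status (including an intermediate stratum
#' that the diagnostic criteria exclude), and records the causal-SNP truth.
#'
#' @param config A [sim_config()].
#' @return An object of class `psm_cohort`: a list with elements
#'   `genotypes` (matrix), `cohort` (tibble with covariates, clinical fields
#'   and `status` in case/control/excluded), `truth` (direct-causal and
#'   BMI-causal rsIDs), `annotation` (rsid-to-gene tibble), `config`, and
#'   `seed_used`.
#' @export
#' @examples
#' ch <- simulate_cohort(sim_config(n_samples = 300, n_snps = 40, seed = 7))
#' table(ch$cohort$status)
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  genotypes <- simulate_genotypes(config)
  causal <- pick_causal(config, colnames(genotypes))
  covs <- simulate_covariates(genotypes, config, causal$bmi_causal)
  covs <- simulate_disease(genotypes, covs, config, causal$direct_causal)
  clin <- simulate_clinical(covs$case, config)
  cohort <- dplyr::bind_cols(covs, clin)
  cohort$status <- dplyr::case_when(
    cohort$case ~ "case",
    cohort$fpg > 100 ~ "excluded",
    TRUE ~ "control"
  )
  cohort$case <- NULL
  info <- snp_info(genotypes)
  structure(
    list(genotypes = genotypes, cohort = cohort,
         truth = list(direct_causal = causal$direct_causal,
                      bmi_causal = causal$bmi_causal),
         annotation = info[, c("rsid", "gene")],
         config = config, seed_used = config$seed),
    class = "psm_cohort"
  )
}

#' @export
print.psm_cohort <- function(x, ...) {
  tab <- table(x$cohort$status)
  cat(sprintf("<psm_cohort> %d samples x %d SNPs (seed %d)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$seed_used))
  cat(sprintf("  status: %s\n",
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  cat(sprintf("  truth: %d direct-causal, %d BMI-causal SNPs\n",
              length(x$truth$direct_causal), length(x$truth$bmi_causal)))
  invisible(x)
}

#' Build a synthetic SNP catalog and gene list for set construction
#'
#' Emulates an external association-catalog input: a mix of truly causal and
#' random SNPs from the cohort, plus the genes containing them. Labelled
#' synthetic; it stands in for a curated catalog file, which real analyses
#' supply as input.
#'
#' @param cohort A `psm_cohort`.
#' @param n_catalog Number of catalog rsIDs.
#' @param frac_causal Fraction of catalog entries drawn from the true causal
#'   sets (the remainder are random SNPs).
#' @param seed RNG seed.
#' @return A list with `rsids` and `genes` character vectors.
#' @export
make_synthetic_catalog <- function(cohort, n_catalog = 30,
                                   frac_causal = 0.5, seed = 1L) {
  all_rsids <- colnames(cohort$genotypes)
  causal <- unique(c(cohort$truth$direct_causal, cohort$truth$bmi_causal))
  with_seed(derive_seed(seed, 6L), {
    n_causal <- min(length(causal), round(frac_causal * n_catalog))
    from_causal <- if (n_causal > 0) sample(causal, n_causal) else character()
    pool <- setdiff(all_rsids, from_causal)
    n_rand <- min(length(pool), n_catalog - n_causal)
    rsids <- sort(c(from_causal, sample(pool, n_rand)))
    ann <- cohort$annotation
    genes <- sort(unique(ann$gene[match(rsids, ann$rsid)]))
    list(rsids = rsids, genes = genes[!is.na(genes)])
  })
}
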