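# psmsnp

Measuring the **pure additive contribution of SNPs** to binary disease risk
prediction, with propensity-score matching to neutralize demographic
confounding.

## The problem

Type 2 diabetes (T2D) risk models usually combine SNP dosages with sex, age
and body mass index (BMI). The natural question — *how much predictive value
do the SNPs add on top of the demographics?* — is biased downward on
unmatched case-control samples whenever a covariate is heritable: genetic
effects that act on disease through BMI are absorbed by the covariate model,
and cases differ demographically from controls to begin with. psmsnp
implements the corrective workflow:

1. **Match** cases and controls 1:1 on the propensity score
   p(χ) = logit⁻¹(γ₀ + γ₁·sex + γ₂·age + γ₃·BMI), using greedy
   nearest-neighbour matching under a caliper (the maximum within-pair score
   difference). The caliper and processing order (largest / smallest /
   random) are chosen by a **replicated sweep**: for each caliper on a grid
   (0–1 by 0.01) the matching is repeated (default 100×) and a cell
   qualifies only if a summary (max / first-quartile / min) of the paired-t
   and Wilcoxon signed-rank p-values on the matched scores exceeds 0.05;
   among qualifying cells the one retaining the most samples wins.
2. **Screen** SNPs on the training samples only (per-SNP logistic scans,
   covariate-adjusted), assembling candidate sets of size k from the scan,
   from an external catalog file, or from catalog genes.
3. **Stabilize** the selection by five-fold CV under stepwise-AUC logistic
   regression (SLR), LASSO (CV-minimum λ) and elastic net (one-SE λ,
   mixing 0.5); *group g* keeps SNPs selected in ≥ g folds.
4. **Evaluate** Δ = AUC(SNPs + covariates) − AUC(covariates) on the held-out
   test third, for every selector × group × predictor combination, on the
   unmatched and matched cohorts.

On a matched cohort the covariate-only AUC sits near 0.5 by construction, so
Δ isolates the SNPs' pure additive contribution.

Because cohort data of this kind are not redistributable, the package
includes a first-class **synthetic cohort generator**: HWE genotypes,
demographics with a tunable heritable BMI component (h²), a logistic disease
model mixing direct and BMI-mediated SNP effects, and clinical glucose
fields consistent with a three-way case/control/excluded diagnostic
classification. Standard genotype QC (call rates, MAF, HWE exact test) and
the diagnostic classifier are included.

## Worked example

```r
library(psmsnp)
library(dplyr)

# A confounded cohort: 1,200 subjects, 150 SNPs, 8 direct-causal SNPs and
# 8 SNPs acting on disease only through BMI (h2_bmi = 0.4).
ch <- simulate_cohort(sim_config(n_samples = 1200, n_snps = 150,
                                 n_direct_causal = 8, n_bmi_causal = 8,
                                 seed = 7))
coh <- filter(ch$cohort, status %in% c("case", "control"))

# Caliper sweep (random order, 10 experiments per caliper) and matching
sw <- run_sweep(coh, sweep_config(caliper_grid = seq(0, 0.3, by = 0.02),
                                  n_experiments = 10, methods = "random",
                                  seed = 7))
select_caliper(sw, summary = "max")
#> # A tibble: 1 x 4
#>   method caliper mean_n_matched p_summary
#>   <chr>    <dbl>          <dbl>     <dbl>
#> 1 random     0.1           588.    0.0682
```

The selected cell retains on average 588 of the analyzed samples while both
homogeneity tests stay non-significant. Matching, splitting 2:1 with pairs
kept intact, scanning the training samples, and evaluating a LASSO-selected,
LASSO-predicted model:

```r
mc <- matched_cohort(coh, sw, 0.1, "random", seed = 7)
covariate_balance(coh); covariate_balance(coh, mc$pairs)
#>   age SMD 0.618 -> 0.006;  bmi SMD 0.393 -> 0.060

variants <- list(
  unmatched = list(genotypes = ch$genotypes, cohort = coh,
                   split = train_test_split(coh, seed = 7)),
  matched = list(genotypes = ch$genotypes, cohort = mc$cohort,
                 split = train_test_split(mc$cohort, seed = 7,
                                          pairs = mc$pairs))
)
sets <- purrr::imap(variants, function(v, vn) {
  rows <- match(v$split$train_ids, rownames(v$genotypes))
  crows <- match(v$split$train_ids, v$cohort$sample_id)
  scan <- single_snp_scan(v$genotypes[rows, ], v$cohort$status[crows],
                          v$cohort[crows, c("sex", "age", "bmi")])
  list(build_kare_set(scan, 40))
})
grid <- run_grid(variants, sets, selection_methods = "lasso",
                 groups = c(1, 5), prediction_methods = "lasso", seed = 7)
best_rows(grid) |>
  select(cohort_variant, group, auc_covariates, auc_snps_covariates, delta)
#> # A tibble: 2 x 5
#>   cohort_variant group auc_covariates auc_snps_covariates  delta
#>   <chr>          <dbl>          <dbl>               <dbl>  <dbl>
#> 1 matched            1          0.455               0.665 0.210
#> 2 unmatched          1          0.695               0.713 0.0176
```

Read: on the unmatched cohort the demographic model is strong (AUC 0.70) and
adding SNPs moves it barely (Δ ≈ 0.02) — much of the genetic signal is
hidden inside the covariates. After matching, the demographic AUC collapses
to ≈ 0.5 and the same machinery reveals a pure additive SNP contribution of
Δ ≈ 0.21.

`autoplot(sw)` draws the sweep (p-value boxes vs caliper with the matched
count overlaid), `plot_balance(coh, mc$pairs)` the before/after covariate
boxplots, and `autoplot(grid)` the best deltas per set and cohort variant.

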