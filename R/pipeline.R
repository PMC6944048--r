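#' Run the full pure-additive-contribution workflow
#'
#' End-to-end protocol: genotype QC, clinical case/control classification,
#' replicated caliper sweep with two selection summaries (producing the
#' unmatched cohort plus `psmmax` and `psmmin` matched variants), training-only
#' association scans, candidate SNP sets, CV stability selection and the full
#' (selector x group x predictor) evaluation grid with its best rows.
#'
#' @param cohort A `psm_cohort` (from [simulate_cohort()] or [read_cohort()]).
#' @param catalog Optional list with `rsids` and `genes` (e.g. from
#'   [make_synthetic_catalog()] or [read_snp_catalog()] /
#'   [read_gene_list()]); enables the catalog-based set recipes.
#' @param set_sizes Candidate-set sizes (e.g. `c(200, 500, 1000)`).
#' @param selection_methods,prediction_methods Subsets of
#'   `c("slr", "lasso", "en")`.
#' @param groups Stability-group indices to evaluate.
#' @param qc A [qc_thresholds()].
#' @param sweep_cfg A [sweep_config()].
#' @param summaries Named character vector mapping variant tags to sweep
#'   summaries; default `c(psmmax = "max", psmmin = "min")`.
#' @param train_fraction Train fraction for every variant (default 2/3).
#' @param k_folds Stability-selection folds.
#' @param en_alpha Elastic-net mixing weight.
#' @param skip_psm Analyze the unmatched cohort only.
#' @param adjusted_scan Covariate-adjust the association scans.
#' @param seed Global seed; every stochastic stage derives its stream from it.
#' @return An object of class `psm_report`: list with `grid`, `best`,
#'   `qc_report`, `calipers`, `status_counts`, `variants` (sample counts),
#'   `seed`.
#' @export
run_full_pipeline <- function(cohort, catalog = NULL,
                              set_sizes = c(200, 500, 1000),
                              selection_methods = c("slr", "lasso", "en"),
                              prediction_methods = c("slr", "lasso", "en"),
                              groups = 1:5,
                              qc = qc_thresholds(),
                              sweep_cfg = NULL,
                              summaries = c(psmmax = "max", psmmin = "min"),
                              train_fraction = 2 / 3, k_folds = 5,
                              en_alpha = 0.5, skip_psm = FALSE,
                              adjusted_scan = TRUE, seed = 1L) {
  stopifnot(inherits(cohort, "psm_cohort"))
  qc_res <- apply_qc(cohort$genotypes, qc)
  g <- qc_res$genotypes
  ph <- cohort$cohort
  ph$status <- classify_t2d(fpg = ph$fpg, hba1c = ph$hba1c, pg2h = ph$pg2h,
                            dm_history = ph$dm_history,
                            onset_age = ph$onset_age)
  status_counts <- table(ph$status)
  analyzed <- dplyr::filter(ph, .data$status %in% c("case", "control") &
                              .data$sample_id %in% rownames(g))
  variants <- list(
    unmatched = list(
      genotypes = g, cohort = analyzed,
      split = train_test_split(analyzed, train_fraction,
                               seed = derive_seed(seed, 71L)),
      pairs = NULL
    )
  )
  calipers <- tibble::tibble(variant = character(), method = character(),
                             caliper = numeric(), mean_n_matched = numeric())
  if (!skip_psm) {
    sweep_cfg <- sweep_cfg %||% sweep_config(seed = derive_seed(seed, 72L))
    sweep <- run_sweep(analyzed, sweep_cfg)
    for (tag in names(summaries)) {
      sel <- tryCatch(select_caliper(sweep, summary = summaries[[tag]]),
                      error = function(e) {
                        warning(sprintf("variant %s skipped: %s", tag,
                                        e$message), call. = FALSE)
                        NULL
                      })
      if (is.null(sel)) next
      mc <- matched_cohort(analyzed, sweep, sel$caliper, sel$method,
                           seed = derive_seed(seed, 73L, match(tag,
                                                               names(summaries))))
      variants[[tag]] <- list(
        genotypes = g, cohort = mc$cohort,
        split = train_test_split(mc$cohort, train_fraction,
                                 seed = derive_seed(seed, 74L),
                                 pairs = mc$pairs),
        pairs = mc$pairs
      )
      calipers <- dplyr::bind_rows(calipers,
                                   dplyr::mutate(sel, variant = tag,
                                                 .before = 1))
    }
  }
  sets_by_variant <- purrr::imap(variants, function(v, vn) {
    tr <- v$split$train_ids
    rows <- match(tr, rownames(v$genotypes))
    crows <- match(tr, v$cohort$sample_id)
    scan <- single_snp_scan(v$genotypes[rows, , drop = FALSE],
                            v$cohort$status[crows],
                            v$cohort[crows, c("sex", "age", "bmi")],
                            adjusted = adjusted_scan)
    purrr::flatten(purrr::map(set_sizes, function(k) {
      sets <- list(build_kare_set(scan, k))
      if (!is.null(catalog$rsids)) {
        sets <- c(sets, list(build_gwas_kare_set(catalog$rsids, scan, k)))
      }
      if (!is.null(catalog$genes) && !is.null(cohort$annotation)) {
        sets <- c(sets, list(build_catagene_set(cohort$annotation,
                                                catalog$genes, scan, k)))
      }
      sets
    }))
  })
  grid <- run_grid(variants, sets_by_variant,
                   selection_methods = selection_methods, groups = groups,
                   prediction_methods = prediction_methods,
                   k_folds = k_folds, en_alpha = en_alpha,
                   seed = derive_seed(seed, 75L))
  structure(list(
    grid = grid, best = best_rows(grid), qc_report = qc_res$report,
    calipers = calipers, status_counts = status_counts,
    variants = purrr::imap(variants, function(v, vn) {
      tibble::tibble(variant = vn, n_train = length(v$split$train_ids),
                     n_test = length(v$split$test_ids))
    }) |> dplyr::bind_rows(),
    seed = seed
  ), class = "psm_report")
}

#' @export
print.psm_report <- function(x, ...) {
  cat(sprintf("<psm_report> %d grid rows, %d best rows (seed %d)\n",
              nrow(x$grid), nrow(x$best), x$seed))
  if (nrow(x$calipers) > 0) {
    cat("selected calipers:\n")
    print(x$calipers)
  }
  print(x$best[, c("cohort_variant", "snp_set", "selection_method", "group",
                   "prediction_method", "auc_covariates",
                   "auc_snps_covariates", "delta")])
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Emits `grid.tsv` (full evaluation grid, deltas at 4 decimals),
#' `best_rows.json`, `qc_report.json` and `calipers.json`, each stamped with
#' the seed.
#'
#' @param report A `psm_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_grid_tsv(report$grid, file.path(dir, "grid.tsv"))
  jsonlite::write_json(list(seed = report$seed, best = report$best),
                       file.path(dir, "best_rows.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = report$seed, report = report$qc_report),
                       file.path(dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = report$seed, calipers = report$calipers),
                       file.path(dir, "calipers.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
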