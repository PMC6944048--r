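#' Configuration for the replicated caliper sweep
#'
#' @param caliper_grid Ascending caliper values; default 0 to 1 in steps of
#'   0.01.
#' @param n_experiments Replicated matchings per (method, caliper) cell;
#'   default 100.
#' @param methods Subset of `c("largest", "smallest", "random")`.
#' @param alpha Significance level for the homogeneity gates.
#' @param seed Base seed; each experiment gets its own derived stream.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(caliper_grid = seq(0, 1, by = 0.01),
                         n_experiments = 100,
                         methods = c("largest", "smallest", "random"),
                         alpha = 0.05, seed = 1L) {
  assert_that(!is.unsorted(caliper_grid) && all(caliper_grid >= 0),
              "caliper_grid must be ascending and nonnegative")
  assert_that(n_experiments >= 1, "n_experiments must be >= 1")
  methods <- match.arg(methods, several.ok = TRUE)
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  structure(list(caliper_grid = caliper_grid,
                 n_experiments = as.integer(n_experiments),
                 methods = methods, alpha = alpha, seed = as.integer(seed)),
            class = "sweep_config")
}

#' Run the replicated caliper sweep
#'
#' Estimates the propensity model once, then for every matching method and
#' caliper on the grid repeats the greedy matching `n_experiments` times under
#' distinct derived RNG streams (governing the random processing order and the
#' tie-break shuffle), recording the paired-t and Wilcoxon p-values on the
#' matched scores and the matched sample count (cases + controls).
#'
#' @param cohort Tibble with `sample_id`, `sex`, `age`, `bmi`, `status`.
#' @param config A [sweep_config()].
#' @return An object of class `psm_sweep`: list with `experiments` (tibble of
#'   method, caliper, experiment, p_t, p_wilcoxon, n_matched), `model`,
#'   `scores`, `config`.
#' @export
run_sweep <- function(cohort, config = sweep_config()) {
  stopifnot(inherits(config, "sweep_config"))
  model <- estimate_propensity(cohort)
  d <- dplyr::filter(cohort, .data$status %in% c("case", "control"))
  s <- propensity_scores(model, d)
  case_s <- s[d$status == "case"]
  ctrl_s <- s[d$status == "control"]
  grid <- tidyr::expand_grid(
    method = config$methods,
    caliper = config$caliper_grid,
    experiment = seq_len(config$n_experiments)
  )
  res <- purrr::pmap(grid, function(method, caliper, experiment) {
    seed_e <- derive_seed(config$seed,
                          match(method, c("largest", "smallest", "random")),
                          round(caliper * 1000), experiment)
    pairs <- greedy_caliper_match(case_s, ctrl_s, caliper,
                                  order_method = method, seed = seed_e)
    bt <- balance_tests(pairs)
    tibble::tibble(p_t = bt$p_t, p_wilcoxon = bt$p_wilcoxon,
                   n_matched = 2L * nrow(pairs))
  })
  experiments <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  structure(list(experiments = experiments, model = model,
                 scores = tibble::tibble(sample_id = d$sample_id,
                                         status = d$status, score = unname(s)),
                 config = config),
            class = "psm_sweep")
}

#' @export
print.psm_sweep <- function(x, ...) {
  cat(sprintf("<psm_sweep> %d methods x %d calipers x %d experiments\n",
              length(x$config$methods), length(x$config$caliper_grid),
              x$config$n_experiments))
  invisible(x)
}

summary_fun <- function(summary) {
  switch(summary,
         max = function(p) max(p),
         first_quartile = function(p) unname(stats::quantile(p, 0.25)),
         min = function(p) min(p))
}

#' Per-cell summary of a caliper sweep
#'
#' For each (method, caliper) cell, applies the chosen summary over the
#' experiments to the per-experiment worse (smaller) of the two homogeneity
#' p-values, and averages the matched sample count. `passes` indicates the
#' homogeneity gate `summary > alpha`.
#'
#' @param x A `psm_sweep`.
#' @param summary `"max"`, `"first_quartile"` or `"min"` over experiments.
#' @param alpha Gate level; defaults to the sweep's configured alpha.
#' @param ... Unused.
#' @return A tibble with columns `method`, `caliper`, `p_summary`,
#'   `mean_n_matched`, `passes`.
#' @export
tidy.psm_sweep <- function(x, summary = c("max", "first_quartile", "min"),
                           alpha = NULL, ...) {
  summary <- match.arg(summary)
  alpha <- alpha %||% x$config$alpha
  f <- summary_fun(summary)
  x$experiments |>
    dplyr::group_by(.data$method, .data$caliper) |>
    dplyr::summarise(
      p_summary = {
        p <- pmin(.data$p_t, .data$p_wilcoxon)
        if (anyNA(p)) NA_real_ else f(p)
      },
      mean_n_matched = mean(.data$n_matched),
      .groups = "drop"
    ) |>
    dplyr::mutate(passes = !is.na(.data$p_summary) & .data$p_summary > alpha)
}

#' @export
glance.psm_sweep <- function(x, ...) {
  tibble::tibble(
    n_methods = length(x$config$methods),
    n_calipers = length(x$config$caliper_grid),
    n_experiments = x$config$n_experiments,
    n_cases = sum(x$scores$status == "case"),
    n_controls = sum(x$scores$status == "control")
  )
}

#' Select the caliper (and method) from a sweep
#'
#' Among cells whose summarized homogeneity p-value exceeds `alpha` (both
#' tests, via the per-experiment minimum), returns the cell with the largest
#' mean matched-sample count — the caliper that loses the fewest samples
#' subject to demographic homogeneity. Ties go to the larger caliper.
#'
#' @inheritParams tidy.psm_sweep
#' @param sweep A `psm_sweep`.
#' @param method Optional: restrict the selection to one matching method.
#' @return A one-row tibble `method`, `caliper`, `mean_n_matched`,
#'   `p_summary`.
#' @export
select_caliper <- function(sweep, summary = c("max", "first_quartile", "min"),
                           alpha = NULL, method = NULL) {
  summary <- match.arg(summary)
  cells <- tidy(sweep, summary = summary, alpha = alpha)
  if (!is.null(method)) cells <- dplyr::filter(cells, .data$method %in% !!method)
  ok <- dplyr::filter(cells, .data$passes)
  if (nrow(ok) == 0) {
    stop("no (method, caliper) cell passes the homogeneity gate; ",
         "largest observed p_summary = ",
         format(max(cells$p_summary, na.rm = TRUE), digits = 3),
         call. = FALSE)
  }
  ok |>
    dplyr::arrange(dplyr::desc(.data$mean_n_matched),
                   dplyr::desc(.data$caliper)) |>
    dplyr::slice(1) |>
    dplyr::select("method", "caliper", "mean_n_matched", "p_summary")
}

#' Build the matched cohort at a chosen (method, caliper)
#'
#' Performs one final greedy matching at the selected cell and subsets the
#' cohort to the matched samples.
#'
#' @param cohort Tibble with `sample_id`, `sex`, `age`, `bmi`, `status`.
#' @param sweep A `psm_sweep` (provides model and scores).
#' @param caliper,order_method The selected cell.
#' @param seed Seed for the final matching.
#' @return A list: `cohort` (matched subset tibble), `pairs` (`psm_pairs`).
#' @export
matched_cohort <- function(cohort, sweep, caliper, order_method,
                           seed = sweep$config$seed) {
  sc <- sweep$scores
  case_s <- stats::setNames(sc$score[sc$status == "case"],
                            sc$sample_id[sc$status == "case"])
  ctrl_s <- stats::setNames(sc$score[sc$status == "control"],
                            sc$sample_id[sc$status == "control"])
  pairs <- greedy_caliper_match(case_s, ctrl_s, caliper,
                                order_method = order_method, seed = seed)
  ids <- c(pairs$case_id, pairs$control_id)
  list(cohort = cohort[match(ids, cohort$sample_id), ], pairs = pairs)
}
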