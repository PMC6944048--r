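#' Plot a caliper sweep
#'
#' Boxplots of the replicated homogeneity p-values (log scale) per caliper,
#' one panel per matching method, with the mean matched-sample count overlaid
#' (rescaled) and the significance level drawn in red.
#'
#' @param object A `psm_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psm_sweep <- function(object, ...) {
  ex <- object$experiments |>
    tidyr::pivot_longer(c("p_t", "p_wilcoxon"), names_to = "test",
                        values_to = "p") |>
    dplyr::mutate(p = pmax(.data$p, 1e-12))
  nm <- object$experiments |>
    dplyr::group_by(.data$method, .data$caliper) |>
    dplyr::summarise(mean_n = mean(.data$n_matched), .groups = "drop")
  sc <- max(nm$mean_n, 1)
  ggplot2::ggplot(ex, ggplot2::aes(x = .data$caliper, y = .data$p)) +
    ggplot2::geom_boxplot(ggplot2::aes(group = interaction(.data$caliper,
                                                           .data$test),
                                       fill = .data$test),
                          outlier.size = 0.3, linewidth = 0.2) +
    ggplot2::geom_line(data = nm,
                       ggplot2::aes(y = 10^(log10(1e-12) *
                                              (1 - .data$mean_n / sc))),
                       colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = object$config$alpha, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~method, ncol = 1) +
    ggplot2::labs(x = "caliper", y = "homogeneity p-value (log scale)",
                  fill = NULL,
                  caption = "green line: mean matched samples (rescaled)") +
    ggplot2::theme_minimal()
}

#' Before/after matching covariate distributions
#'
#' Boxplots of covariates for cases and controls before matching (full
#' cohort) and after matching (matched subsample), one facet per covariate.
#'
#' @param cohort Tibble with `sample_id`, covariates and `status`.
#' @param pairs A `psm_pairs`.
#' @param covariates Covariate columns to show.
#' @return A ggplot object.
#' @export
plot_balance <- function(cohort, pairs, covariates = c("age", "bmi")) {
  before <- dplyr::filter(cohort, .data$status %in% c("case", "control")) |>
    dplyr::mutate(period = "before PSM")
  matched_ids <- c(pairs$case_id, pairs$control_id)
  after <- dplyr::filter(cohort, .data$sample_id %in% matched_ids) |>
    dplyr::mutate(period = "after PSM")
  dplyr::bind_rows(before, after) |>
    dplyr::mutate(period = factor(.data$period,
                                  c("before PSM", "after PSM"))) |>
    tidyr::pivot_longer(dplyr::all_of(covariates), names_to = "covariate") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$period, y = .data$value,
                                 fill = .data$status)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~covariate, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation grid
#'
#' Best delta-AUC per SNP set and cohort variant.
#'
#' @param object A `psm_grid` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psm_grid <- function(object, ...) {
  best_rows(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$snp_set, y = .data$delta,
                                 fill = .data$cohort_variant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "best delta AUC (SNPs + covariates vs covariates)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
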