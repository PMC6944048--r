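#' Area under the ROC curve (Mann-Whitney form)
#'
#' The fraction of (case, control) pairs in which the case scores higher,
#' counting ties as 1/2 — computed from midranks, which equals the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (1/TRUE = case).
#' @return An object of class `psm_roc` with `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' auc(c(0.8, 0.6, 0.6, 0.4), c(1, 1, 0, 0))$auc  # 0.875
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  a <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(auc = a, n_pos = n_pos, n_neg = n_neg), class = "psm_roc")
}

#' @export
print.psm_roc <- function(x, ...) {
  cat(sprintf("<psm_roc> AUC = %.4f (%d cases vs %d controls)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Empirical ROC curve points
#'
#' @inheritParams auc
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(s, fromLast = TRUE)   # one point per distinct threshold
  tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / sum(!labels)),
    tpr = c(0, tp[last] / sum(labels))
  )
}
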