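#' Paired t-test p-value
#'
#' Two-sided one-sample t-test on the pairwise differences. By convention,
#' all-zero differences give p = 1 (perfectly balanced pairs) and nonzero
#' constant differences give p = 0 (a deterministic shift).
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return A two-sided p-value.
#' @export
paired_t_test <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 2,
              "x and y must be paired vectors of length >= 2")
  d <- x - y
  if (all(d == 0)) return(1.0)
  if (stats::sd(d) <= 1e-12 * max(abs(d))) return(0.0)
  unname(stats::t.test(d)$p.value)
}

#' Wilcoxon signed-rank test p-value
#'
#' Two-sided test on the pairwise differences after zero removal. For n <= 25
#' remaining pairs the exact null distribution of the positive-rank sum is
#' computed by convolution over sign assignments (midranks, so ties are
#' handled exactly); above that, a normal approximation with tie and
#' continuity corrections is used. All-zero differences give p = 1.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return A two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  assert_that(length(x) == length(y) && length(x) >= 2,
              "x and y must be paired vectors of length >= 2")
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1.0)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))      # doubled midranks are integers
    total <- sum(r2)
    cnt <- numeric(total + 1)           # cnt[s + 1] = #sign vectors with sum s
    cnt[1] <- 1
    for (ri in r2) {
      cnt <- cnt + c(rep(0, ri), cnt[seq_len(total + 1 - ri)])
    }
    pr <- cnt / 2^n
    sums <- 0:total
    w2 <- round(2 * w)
    p_le <- sum(pr[sums <= w2 + 1e-9])
    p_ge <- sum(pr[sums >= w2 - 1e-9])
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(1.0)
  z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}
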