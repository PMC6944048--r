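# Independent oracles used across the suite. Each re-derives its expected
# value by a route different from the package implementation (absolute
# enumeration, brute force, or direct numerical optimization).

# HWE exact test by absolute enumeration: unnormalized multinomial /
# hypergeometric probabilities P(h | n, allele counts) computed from
# factorials directly (the package normalizes relative weights instead).
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  r <- min(na, nb)
  if (r == 0) return(1)
  hs <- seq(r %% 2, r, by = 2)
  pr <- vapply(hs, function(h) {
    nrr <- (r - h) / 2
    ncc <- n - h - nrr
    if (ncc < 0) return(0)
    exp(lfactorial(n) - lfactorial(nrr) - lfactorial(h) - lfactorial(ncc) +
          h * log(2) + lfactorial(max(na, nb)) + lfactorial(r) -
          lfactorial(2 * n))
  }, numeric(1))
  stopifnot(abs(sum(pr) - 1) < 1e-9)
  obs <- pr[hs == n_ab]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# Exact two-sided Wilcoxon signed-rank p-value by full enumeration of the
# 2^n sign vectors (midranks for ties).
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  stopifnot(n <= 14)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- drop(signs %*% r)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force greedy caliper matcher replaying the package's processing
# order and tie-break semantics with a naive double loop.
oracle_greedy_match <- function(case_scores, control_scores, caliper,
                                order_method, seed = NULL) {
  ds <- psmsnp:::derive_seed
  ws <- psmsnp:::with_seed
  if (is.null(seed)) {
    case_perm <- seq_along(case_scores)
    ctrl_perm <- seq_along(control_scores)
  } else {
    case_perm <- ws(ds(seed, 21L), sample(seq_along(case_scores)))
    ctrl_perm <- ws(ds(seed, 22L), sample(seq_along(control_scores)))
  }
  case_idx <- switch(order_method,
    largest = case_perm[order(case_scores[case_perm], decreasing = TRUE)],
    smallest = case_perm[order(case_scores[case_perm])],
    random = case_perm)
  ctrl_s <- control_scores[ctrl_perm]
  used <- rep(FALSE, length(ctrl_s))
  out <- list()
  for (i in case_idx) {
    best <- Inf; bj <- NA
    for (j in seq_along(ctrl_s)) {
      if (used[j]) next
      dd <- abs(case_scores[i] - ctrl_s[j])
      if (dd < best - 1e-12) { best <- dd; bj <- j }
    }
    if (!is.na(bj) && best <= caliper + 1e-12) {
      used[bj] <- TRUE
      out[[length(out) + 1]] <- c(names(case_scores)[i],
                                  names(control_scores)[ctrl_perm[bj]])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(case_id = character(), control_id = character()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(case_id = m[, 1], control_id = m[, 2])
}

# Penalized binomial log-likelihood objective (sum scale) used to check
# fit_logistic against a direct numerical optimizer.
penalized_objective <- function(par, x, y, lambda1, lambda2, penalized_idx) {
  eta <- par[1] + drop(x %*% par[-1])
  nll <- -sum(y * eta - log1p(exp(eta)))
  b <- par[-1][penalized_idx]
  nll + lambda1 * sum(abs(b)) + lambda2 * sum(b^2)
}

oracle_penalized_fit <- function(x, y, lambda1, lambda2, penalized_idx) {
  best <- NULL
  for (s in 1:5) {
    start <- psmsnp:::with_seed(s, rnorm(ncol(x) + 1, 0, 0.3))
    o <- stats::optim(start, penalized_objective, x = x, y = y,
                      lambda1 = lambda1, lambda2 = lambda2,
                      penalized_idx = penalized_idx,
                      method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    o <- stats::optim(o$par, penalized_objective, x = x, y = y,
                      lambda1 = lambda1, lambda2 = lambda2,
                      penalized_idx = penalized_idx,
                      method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best
}
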