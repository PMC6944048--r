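#' Inverse logit
#' @param x Numeric vector of log-odds.
#' @return Probabilities in (0, 1).
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Logit
#' @param p Probabilities in (0, 1).
#' @return Log-odds.
#' @export
logit <- function(p) log(p / (1 - p))

# Derive a child RNG seed from a parent seed and stream indices.
# Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 1103515245 + 12345 + as.double(k) * 2654435761) %% 2147483647
  }
  as.integer(s)
}

# Evaluate an expression under a local RNG state (does not disturb the
# caller's stream).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Standardized mean difference between two groups (pooled SD denominator).
smd <- function(x_case, x_control) {
  sp <- sqrt((stats::var(x_case) + stats::var(x_control)) / 2)
  if (!is.finite(sp) || sp == 0) return(0)
  (mean(x_case) - mean(x_control)) / sp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
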