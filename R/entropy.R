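# Complexity measures used as window features. All are defined to return a
# finite value on degenerate inputs (constant or very short series) rather
# than NaN; the conventions are documented on each function.

#' Sample entropy
#'
#' `-log(A / B)` where `B` counts pairs of length-`m` templates within
#' Chebyshev distance `r` of each other (self-matches excluded) and `A` the
#' corresponding count for length-`m + 1` templates. Conventions for
#' degenerate inputs: a constant series has entropy 0 (every template
#' matches); if no `m`-templates match (`B = 0`) the entropy is 0 by the
#' same "no surprise measurable" convention; if `B > 0` but no
#' `(m+1)`-template matches, the estimate is capped at
#' `-log(2 / ((N - m - 1) (N - m)))`, the largest value estimable from a
#' series of length `N`.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; default `0.2 * sd(x)`.
#' @return Non-negative scalar.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2) return(NA_real_)
  if (is.na(r)) return(NA_real_)
  # both template lengths use the same n - m starting positions
  # (Richman & Moorman convention), guaranteeing A <= B
  count_matches <- function(mm) {
    nt <- n - m
    tm <- matrix(0, nt, mm)
    for (j in seq_len(mm)) tm[, j] <- x[j:(j + nt - 1)]
    cnt <- 0L
    for (i in seq_len(nt - 1)) {
      d <- abs(tm[(i + 1):nt, , drop = FALSE] -
                 matrix(tm[i, ], nt - i, mm, byrow = TRUE))
      cnt <- cnt + sum(apply(d, 1, max) <= r)
    }
    cnt
  }
  # templates of length m and m+1 over a common range so A <= B
  b <- count_matches(m)
  a <- count_matches(m + 1)
  if (b == 0) return(0)
  if (a == 0) return(-log(2 / ((n - m - 1) * (n - m))))
  -log(a / b)
}

#' Permutation entropy
#'
#' Shannon entropy of the distribution of ordinal patterns of `order`
#' consecutive values (ties broken by position), normalized by
#' `log(order!)` so the result lies in `[0, 1]`. A constant series has a
#' single pattern and entropy 0.
#'
#' @param x Numeric vector.
#' @param order Pattern length (default 3).
#' @param delay Lag between pattern elements (default 1).
#' @return Scalar in `[0, 1]`.
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  n <- length(x) - (order - 1) * delay
  if (n < 1) return(NA_real_)
  pats <- vapply(seq_len(n), function(i) {
    v <- x[i + (0:(order - 1)) * delay]
    paste(rank(v, ties.method = "first"), collapse = "")
  }, character(1))
  p <- table(pats) / n
  h <- -sum(p * log(p))
  h / log(factorial(order))
}

#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension of a series from the slope of
#' `log(L(k))` versus `log(1/k)`, where `L(k)` is the normalized mean curve
#' length at scale `k` in Higuchi's construction, `k = 1..k_max`. A series
#' with zero curve length at every scale (a constant) returns 1 (the
#' dimension of a smooth line).
#'
#' @param x Numeric vector.
#' @param k_max Largest scale (default 8).
#' @return Scalar, typically in `[1, 2]`.
#' @export
higuchi_fd <- function(x, k_max = 8) {
  n <- length(x)
  if (n < k_max + 2) return(NA_real_)
  lk <- numeric(k_max)
  for (kk in seq_len(k_max)) {
    lm_ <- numeric(kk)
    for (m in seq_len(kk)) {
      idx <- seq(m, n, by = kk)
      if (length(idx) < 2) { lm_[m] <- NA; next }
      lm_[m] <- sum(abs(diff(x[idx]))) * (n - 1) /
        ((length(idx) - 1) * kk) / kk
    }
    lk[kk] <- mean(lm_, na.rm = TRUE)
  }
  if (all(lk == 0)) return(1)
  ok <- lk > 0
  if (sum(ok) < 2) return(1)
  stats::coef(stats::lm(log(lk[ok]) ~ log(1 / seq_len(k_max)[ok])))[[2]]
}
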