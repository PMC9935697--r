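# Independent brute-force oracles, written separately from the package
# implementations they check.

# AUROC by exhaustive positive-negative pair counting, ties worth 1/2.
oracle_auc <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Operating point by exhaustive scan over every candidate threshold.
oracle_operating_point <- function(labels, probs) {
  cand <- c(Inf, sort(unique(probs), decreasing = TRUE))
  best <- NULL
  for (t in cand) {
    sens <- mean(probs[labels == 1] >= t)
    spec <- mean(probs[labels == 0] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12) ||
        (abs(j - best$j) <= 1e-12 && abs(sens - best$sens) <= 1e-12 &&
         t < best$t)) {
      best <- list(j = j, sens = sens, spec = spec, t = t)
    }
  }
  best
}

# Sample entropy by direct double-loop template counting
# (Richman & Moorman: both template lengths over the first n - m starts).
oracle_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  count <- function(mm) {
    cnt <- 0
    for (i in 1:(n - m - 1)) {
      for (j in (i + 1):(n - m)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) {
          cnt <- cnt + 1
        }
      }
    }
    cnt
  }
  b <- count(m); a <- count(m + 1)
  if (b == 0) return(0)
  if (a == 0) return(-log(2 / ((n - m - 1) * (n - m))))
  -log(a / b)
}

# Stratified bootstrap percentile CI for the AUROC.
oracle_bootstrap_ci <- function(labels, probs, n_boot = 2000,
                                level = 0.95) {
  ipos <- which(labels == 1); ineg <- which(labels == 0)
  stats <- replicate(n_boot, {
    idx <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
    rk <- rank(probs[idx])
    n1 <- length(ipos); n0 <- length(ineg)
    (sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  unname(stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2)))
}
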