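# Orthogonal periodized discrete wavelet transform with the Daubechies-4
# (8-tap) filter pair. Implemented here because the analysis needs only
# this one transform: a multi-level periodized decomposition, soft
# thresholding of the detail coefficients, and exact reconstruction.

# Daubechies-4 scaling (low-pass) filter, orthonormal.
db4_lo <- c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114,
            0.030841381835986965, 0.032883011666982945,
            -0.010597401784997278)
db4_hi <- rev(db4_lo) * c(1, -1)  # quadrature mirror: g_n = (-1)^n h_{L-1-n}

dwt_step <- function(x, lo = db4_lo, hi = db4_hi) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  L <- length(lo)
  idx <- outer(2 * (seq_len(n / 2) - 1), seq_len(L) - 1, "+") %% n + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = as.numeric(xm %*% lo), detail = as.numeric(xm %*% hi))
}

idwt_step <- function(approx, detail, lo = db4_lo, hi = db4_hi) {
  n <- 2 * length(approx)
  L <- length(lo)
  x <- numeric(n)
  for (kk in seq_along(approx)) {
    pos <- (2 * (kk - 1) + seq_len(L) - 1) %% n + 1
    x[pos] <- x[pos] + approx[kk] * lo + detail[kk] * hi
  }
  x
}

#' Multi-level periodized Daubechies-4 wavelet decomposition
#'
#' Decomposes a numeric vector into approximation coefficients at the
#' coarsest level and detail coefficients at levels `1..level`, using the
#' orthonormal 8-tap Daubechies-4 filter pair with periodic boundary
#' handling. Vectors whose length is not divisible by `2^level` are padded
#' by repeating the last value; [idwt_db4()] trims the padding back.
#'
#' @param x Numeric vector without `NA`.
#' @param level Decomposition depth (>= 1).
#' @return List with `approx`, `details` (list, level 1 first), `level`,
#'   `n` (original length).
#' @export
dwt_db4 <- function(x, level = 2) {
  stopifnot(level >= 1, !any(is.na(x)))
  n <- length(x)
  blk <- 2^level
  if (n < blk) stop("vector too short for a level-", level,
                    " decomposition", call. = FALSE)
  pad <- (blk - n %% blk) %% blk
  xp <- c(x, rep(x[n], pad))
  details <- vector("list", level)
  a <- xp
  for (l in seq_len(level)) {
    st <- dwt_step(a)
    details[[l]] <- st$detail
    a <- st$approx
  }
  list(approx = a, details = details, level = level, n = n)
}

#' @rdname dwt_db4
#' @param w A decomposition from [dwt_db4()].
#' @export
idwt_db4 <- function(w) {
  a <- w$approx
  for (l in rev(seq_len(w$level))) {
    a <- idwt_step(a, w$details[[l]])
  }
  a[seq_len(w$n)]
}

#' Wavelet denoising of a minute-binned window
#'
#' Removes high-frequency noise by a level-`level` Daubechies-4 discrete
#' wavelet transform with soft thresholding of all detail coefficients at
#' the universal threshold `sigma * sqrt(2 log n)`, where `sigma` is the
#' robust MAD estimate from the finest-level details. Interior `NA` runs of
#' at most `interp_gap` bins are linearly interpolated first; if longer
#' gaps (or missing edges) remain, only the longest contiguous finite
#' segment is denoised and the rest stays `NA`. Returns a vector of the
#' same length as the input; segments shorter than `2^level` are returned
#' unchanged.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param level Decomposition depth (default 2).
#' @param interp_gap Longest interior gap to interpolate before the
#'   transform.
#' @return Denoised vector, same length as `x`.
#' @export
denoise_dwt <- function(x, level = 2, interp_gap = 5) {
  n <- length(x)
  if (n == 0) return(x)
  obs <- which(!is.na(x))
  if (length(obs) < 2) return(x)
  # interpolate short interior gaps
  xi <- x
  gaps <- rle(is.na(x))
  ends <- cumsum(gaps$lengths); starts <- ends - gaps$lengths + 1
  for (j in seq_along(gaps$lengths)) {
    if (gaps$values[j] && gaps$lengths[j] <= interp_gap &&
        starts[j] > obs[1] && ends[j] < obs[length(obs)]) {
      idx <- starts[j]:ends[j]
      xi[idx] <- stats::approx(obs, x[obs], xout = idx)$y
    }
  }
  # longest contiguous finite segment
  seg <- rle(!is.na(xi))
  seg_ends <- cumsum(seg$lengths); seg_starts <- seg_ends - seg$lengths + 1
  fin <- which(seg$values)
  if (length(fin) == 0) return(x)
  best <- fin[which.max(seg$lengths[fin])]
  idx <- seg_starts[best]:seg_ends[best]
  if (length(idx) < 2^level) return(xi)
  w <- dwt_db4(xi[idx], level = level)
  sigma <- stats::mad(w$details[[1]], center = 0)
  lambda <- sigma * sqrt(2 * log(length(idx)))
  soft <- function(d) sign(d) * pmax(abs(d) - lambda, 0)
  w$details <- lapply(w$details, soft)
  out <- xi
  out[idx] <- idwt_db4(w)
  out
}
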