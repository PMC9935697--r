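#' Feature extraction configuration
#'
#' The default feature set contains 16 measures spanning the temporal and
#' complexity domains: mean, median, standard deviation, interquartile
#' range, skewness, kurtosis, minimum, maximum, root-mean-square of
#' successive differences (rmssd), lag-1 autocorrelation, linear-trend
#' slope, number of mean crossings, sample entropy, permutation entropy,
#' Higuchi fractal dimension and a low/high spectral power ratio. The set
#' is fully configurable; the configuration is carried into run metadata by
#' downstream objects.
#'
#' @param wavelet_level DWT decomposition depth for denoising (default 2).
#' @param interp_gap Longest interior gap (bins) interpolated before the
#'   DWT.
#' @param entropy_m,entropy_r_frac Sample-entropy embedding dimension and
#'   tolerance as a fraction of the series SD (defaults 2 and 0.2).
#' @param feature_set Named list of functions `x -> scalar`; defaults to
#'   [default_feature_set()].
#' @return A list of class `nv_feature_config`.
#' @export
feature_config <- function(wavelet_level = 2, interp_gap = 5,
                           entropy_m = 2, entropy_r_frac = 0.2,
                           feature_set = NULL) {
  if (is.null(feature_set)) {
    feature_set <- default_feature_set(entropy_m, entropy_r_frac)
  }
  stopifnot(wavelet_level >= 1, length(feature_set) >= 1,
            !is.null(names(feature_set)))
  structure(list(wavelet_level = wavelet_level, interp_gap = interp_gap,
                 entropy_m = entropy_m, entropy_r_frac = entropy_r_frac,
                 feature_set = feature_set),
            class = "nv_feature_config")
}

#' Default 16-feature set
#'
#' @param entropy_m,entropy_r_frac Sample-entropy parameters.
#' @return Named list of 16 feature functions. Degenerate (constant)
#'   inputs yield defined values: sd/rmssd/crossings 0, skewness/kurtosis
#'   0, lag-1 autocorrelation 0, entropies 0, Higuchi dimension 1,
#'   spectral ratio 1.
#' @export
default_feature_set <- function(entropy_m = 2, entropy_r_frac = 0.2) {
  finite0 <- function(v, fallback = 0) {
    if (!is.finite(v)) fallback else v
  }
  list(
    mean = function(x) mean(x),
    median = function(x) stats::median(x),
    sd = function(x) stats::sd(x),
    iqr = function(x) stats::IQR(x),
    skewness = function(x) finite0(e1071::skewness(x)),
    kurtosis = function(x) finite0(e1071::kurtosis(x)),
    min = function(x) min(x),
    max = function(x) max(x),
    rmssd = function(x) if (length(x) < 2) 0 else sqrt(mean(diff(x)^2)),
    acf1 = function(x) {
      if (stats::sd(x) == 0 || length(x) < 3) return(0)
      finite0(stats::cor(x[-length(x)], x[-1]))
    },
    slope = function(x) {
      if (length(x) < 2) return(0)
      as.numeric(stats::coef(stats::lm(x ~ seq_along(x)))[2])
    },
    mean_crossings = function(x) {
      s <- sign(x - mean(x)); s <- s[s != 0]
      if (length(s) < 2) 0 else sum(diff(s) != 0)
    },
    sample_entropy = function(x) {
      v <- sample_entropy(x, m = entropy_m,
                          r = entropy_r_frac * stats::sd(x))
      if (is.na(v)) 0 else v
    },
    permutation_entropy = function(x) {
      v <- permutation_entropy(x)
      if (is.na(v)) 0 else v
    },
    higuchi_fd = function(x) {
      v <- higuchi_fd(x)
      if (is.na(v)) 1 else v
    },
    spectral_ratio = function(x) spectral_power_ratio(x)
  )
}

#' Low/high spectral power ratio
#'
#' Ratio of periodogram power at frequencies up to `split` cycles/bin
#' (slow fluctuations, periods above 10 minutes on minute bins) to the
#' power above it. A constant series returns 1 (both bands empty).
#'
#' @param x Numeric vector.
#' @param split Band split in cycles per bin (default 0.1).
#' @return Positive scalar.
#' @export
spectral_power_ratio <- function(x, split = 0.1) {
  n <- length(x)
  if (n < 8) return(1)
  p <- Mod(stats::fft(x - mean(x))[2:floor(n / 2)])^2
  f <- (1:(floor(n / 2) - 1)) / n
  eps <- 1e-12
  (sum(p[f <= split]) + eps) / (sum(p[f > split]) + eps)
}

#' Compute the configured features of one denoised window
#'
#' @param x Numeric vector (a denoised, gap-free segment); an empty vector
#'   or one of `NA`s yields all-`NA` features.
#' @param cfg An [feature_config()].
#' @return Named numeric vector, one entry per configured feature.
#' @export
#' @examples
#' compute_features(c(1, 2, 3, 4, 5))[["mean"]]
compute_features <- function(x, cfg = feature_config()) {
  nm <- names(cfg$feature_set)
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  }
  vapply(cfg$feature_set, function(f) as.numeric(f(x)), numeric(1))
}

#' Build the samples-by-(signal, feature) matrix
#'
#' Denoises each present signal of each non-excluded windowed sample with
#' the discrete wavelet transform and maps the window to one row of
#' features. Columns are the active variable subset's signals crossed with
#' the configured features, named `signal__feature`, in deterministic
#' order; all features of a signal that is absent (or fails the presence
#' rule) for a sample are missing in that row. If long gaps survive
#' imputation, features are computed on the longest contiguous segment.
#'
#' @param windows An `nv_windows` from [preprocess_cohort()].
#' @param subset `"hospital"`, `"icu"` or `"neuro"`; the neuro subset is
#'   not available for ICH cohorts (those signals are not recorded in that
#'   group).
#' @param cfg An [feature_config()].
#' @return Tibble with id columns `sample_id, patient_id, group, score,
#'   category` and one numeric column per (signal, feature) pair.
#' @export
build_feature_matrix <- function(windows, subset = c("hospital", "icu",
                                                     "neuro"),
                                 cfg = feature_config()) {
  subset <- match.arg(subset)
  stopifnot(inherits(windows, "nv_windows"))
  groups <- unique(windows$samples$group)
  if (subset == "neuro" && any(groups == "ICH")) {
    stop("the neuro-ICU variable subset is not available for ICH cohorts",
         call. = FALSE)
  }
  sigs <- variable_subset(subset)
  feats <- names(cfg$feature_set)
  cols <- as.vector(outer(sigs, feats, paste, sep = "__"))
  keep <- windows$samples[!windows$samples$excluded, ]
  rows <- vector("list", nrow(keep))
  for (i in seq_len(nrow(keep))) {
    sid <- keep$sample_id[i]
    vals <- windows$values[windows$values$sample_id == sid, ]
    pres <- windows$presence[windows$presence$sample_id == sid, ]
    row <- stats::setNames(rep(NA_real_, length(cols)), cols)
    for (sg in sigs) {
      ok <- pres$present[pres$signal == sg]
      if (length(ok) != 1 || !ok) next
      v <- vals$value[vals$signal == sg][order(vals$bin[vals$signal == sg])]
      den <- denoise_dwt(v, level = cfg$wavelet_level,
                         interp_gap = cfg$interp_gap)
      seg <- longest_finite_segment(den)
      if (length(seg) < 2^cfg$wavelet_level) next
      row[paste(sg, feats, sep = "__")] <- compute_features(seg, cfg)
    }
    rows[[i]] <- tibble::as_tibble(as.list(row))
  }
  out <- dplyr::bind_cols(
    keep[, c("sample_id", "patient_id", "group", "score", "category")],
    dplyr::bind_rows(rows)
  )
  attr(out, "subset") <- subset
  attr(out, "feature_config") <- cfg
  out
}

longest_finite_segment <- function(x) {
  if (all(is.na(x))) return(numeric(0))
  seg <- rle(!is.na(x))
  ends <- cumsum(seg$lengths); starts <- ends - seg$lengths + 1
  fin <- which(seg$values)
  best <- fin[which.max(seg$lengths[fin])]
  x[starts[best]:ends[best]]
}
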