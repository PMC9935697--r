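#' Windowing and exclusion configuration
#'
#' Parameters of pre-assessment window extraction. The default window uses
#' the signal recorded from 200 down to 60 minutes before each assessment
#' (half-open interval `[t - 200 min, t - 60 min)`, 140 one-minute bins),
#' chosen so the window ends before sedation is typically lifted ahead of
#' the morning examination. An assessment is excluded when all recorded
#' variables are missing for more than `exclusion_missing_frac` of the
#' window; a single signal counts as present for a sample when it is
#' non-missing for at least `presence_min_frac` of the window.
#'
#' @param window_start_min,window_end_min Window bounds in minutes before
#'   the assessment; must satisfy `window_start_min > window_end_min >= 0`.
#' @param exclusion_missing_frac All-variable missing fraction above which a
#'   sample is excluded (default 0.80).
#' @param presence_min_frac Minimum per-signal non-missing fraction for the
#'   signal to count as present (default 0.80).
#' @param bin_width_min Resampling bin width in minutes (default 1).
#' @param agg Bin aggregation, `"mean"` (default) or `"median"`.
#' @return A list of class `nv_window_config`.
#' @export
window_config <- function(window_start_min = 200, window_end_min = 60,
                          exclusion_missing_frac = 0.80,
                          presence_min_frac = 0.80,
                          bin_width_min = 1, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  if (!(window_start_min > window_end_min && window_end_min >= 0)) {
    stop("need window_start_min > window_end_min >= 0", call. = FALSE)
  }
  if (exclusion_missing_frac <= 0 || exclusion_missing_frac > 1 ||
      presence_min_frac <= 0 || presence_min_frac > 1) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  structure(list(window_start_min = window_start_min,
                 window_end_min = window_end_min,
                 exclusion_missing_frac = exclusion_missing_frac,
                 presence_min_frac = presence_min_frac,
                 bin_width_min = bin_width_min, agg = agg),
            class = "nv_window_config")
}

#' Resample a raw series to non-overlapping minute bins
#'
#' Bins are aligned to epoch minutes (of width `bin_width_min`); the bin
#' value is the arithmetic mean (or median) of the in-bin samples, and a
#' bin with no samples is missing. The output covers the full grid from the
#' first to the last sample.
#'
#' @param series Tibble with `time` (POSIXct) and `value`; times must be
#'   non-decreasing.
#' @param bin_width_min Bin width in minutes.
#' @param agg `"mean"` or `"median"`.
#' @return Tibble `bin_start` (POSIXct), `value` on the complete grid.
#' @export
resample_bins <- function(series, bin_width_min = 1,
                          agg = c("mean", "median")) {
  agg <- match.arg(agg)
  if (nrow(series) == 0) {
    return(tibble::tibble(bin_start = as.POSIXct(character(), tz = "UTC"),
                          value = numeric()))
  }
  t_num <- as.numeric(series$time)
  if (is.unsorted(t_num)) {
    stop("series timestamps must be sorted", call. = FALSE)
  }
  w <- bin_width_min * 60
  bin <- floor(t_num / w)
  f <- if (agg == "mean") mean else stats::median
  agg_tbl <- series |>
    dplyr::mutate(.bin = bin) |>
    dplyr::group_by(.data$.bin) |>
    dplyr::summarise(value = if (all(is.na(.data$value))) NA_real_
                     else f(.data$value[!is.na(.data$value)]),
                     .groups = "drop")
  grid <- tibble::tibble(.bin = seq(min(bin), max(bin)))
  out <- dplyr::left_join(grid, agg_tbl, by = ".bin")
  tibble::tibble(
    bin_start = as.POSIXct(out$.bin * w, origin = "1970-01-01", tz = "UTC"),
    value = out$value
  )
}

#' Remove clinically implausible values from a minute series
#'
#' Values outside the signal's inclusive clinical range are set to missing;
#' in-range values (including values exactly on a bound) are unchanged.
#'
#' @param x Numeric vector of minute values (may contain `NA`).
#' @param signal Signal name; must have a configured range.
#' @param ranges Tibble of ranges as from [clinical_ranges()].
#' @return `x` with out-of-range entries set to `NA`.
#' @export
filter_outliers <- function(x, signal, ranges = clinical_ranges()) {
  row <- ranges[ranges$signal == signal, ]
  if (nrow(row) != 1) {
    stop("no clinical range configured for signal '", signal, "'",
         call. = FALSE)
  }
  x[!is.na(x) & (x < row$lower | x > row$upper)] <- NA_real_
  x
}

#' Lag-embedded k-nearest-neighbour imputation with Fourier detrending
#'
#' Fills interior missing points of a minute series from observed stretches
#' with a similar local shape. The series is first detrended by its dominant
#' Fourier component (a single sinusoid fitted by least squares at the
#' periodogram-dominant frequency of the linearly interpolated series); each
#' missing point's residual neighbourhood pattern (the `n_lags` residuals on
#' each side) is then matched by Euclidean distance against all fully
#' observed patterns, and the point is filled with the mean of the `k`
#' nearest patterns' centre values plus the sinusoid. Gap runs longer than
#' `max_gap` bins, leading/trailing missingness, and fully missing series
#' are left untouched; observed values are never altered. A series with
#' fewer than `k` observed points is passed through unchanged.
#'
#' @param x Numeric vector (minute series) with `NA` for missing.
#' @param k Number of neighbour patterns (>= 1).
#' @param n_lags Lags on each side of the embedded pattern.
#' @param max_gap Longest gap run (in bins) that will be imputed.
#' @return `x` with eligible interior gaps filled.
#' @export
impute_lagged_knn <- function(x, k = 5, n_lags = 10, max_gap = 10) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  n <- length(x)
  obs <- !is.na(x)
  if (sum(obs) < k || all(obs) || !any(obs)) return(x)
  first_o <- which(obs)[1]; last_o <- which(obs)[sum(obs)]

  # dominant-Fourier-component detrend on the interpolated interior
  interior <- first_o:last_o
  xi <- stats::approx(which(obs), x[obs], xout = interior)$y
  trend <- rep(mean(xi), n)
  if (length(xi) >= 8) {
    sp <- stats::fft(xi - mean(xi))
    m <- length(xi)
    mag <- Mod(sp[2:floor(m / 2)])
    if (length(mag) > 0 && max(mag) > 0) {
      fdom <- which.max(mag) / m       # cycles per bin
      tt <- seq_len(n)
      fit <- stats::lm(x ~ sin(2 * pi * fdom * tt) +
                         cos(2 * pi * fdom * tt),
                       data = data.frame(x = x, tt = tt))
      trend <- as.numeric(stats::predict(
        fit, newdata = data.frame(tt = seq_len(n))))
    }
  }
  r <- x - trend

  runs <- rle(!obs)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  fill_idx <- integer(0)
  for (j in seq_along(runs$lengths)) {
    if (runs$values[j] && runs$lengths[j] <= max_gap &&
        starts[j] > first_o && ends[j] < last_o) {
      fill_idx <- c(fill_idx, starts[j]:ends[j])
    }
  }
  if (length(fill_idx) == 0) return(x)

  w <- n_lags
  offsets <- c(-(w:1), 1:w)  # symmetric pattern, centre excluded
  centers <- (w + 1):(n - w)
  if (length(centers) == 0) return(x)
  emb <- vapply(offsets, function(o) r[centers + o],
                numeric(length(centers)))
  cand <- obs[centers] & !apply(is.na(emb), 1, any)
  out <- x
  for (i in fill_idx) {
    if (i <= w || i > n - w) next
    q <- r[i + offsets]
    ok <- !is.na(q)
    if (sum(ok) < 2) next
    pool <- which(cand)
    if (length(pool) < 1) next
    d2 <- colSums((t(emb[pool, ok, drop = FALSE]) - q[ok])^2)
    nb <- pool[order(d2)][seq_len(min(k, length(pool)))]
    out[i] <- mean(r[centers[nb]]) + trend[i]
  }
  out
}

#' Extract one pre-assessment window from a patient's minute series
#'
#' Collects, for each recorded signal, the 140 one-minute bins (under the
#' default configuration) whose bin start lies in
#' `[t - window_start_min, t - window_end_min)` relative to the assessment
#' time `t`. Computes the per-signal presence mask (non-missing fraction at
#' least `presence_min_frac`) and the exclusion flag (pooled missing
#' fraction across all recorded signals above `exclusion_missing_frac`).
#' An assessment with no recorded data in the window is excluded, not an
#' error.
#'
#' @param minute_series Tibble `signal, bin_start, value` for one patient
#'   (already resampled/imputed/filtered).
#' @param assess_time POSIXct assessment time.
#' @param cfg An [window_config()].
#' @return List with `values` (tibble `signal, bin, value`, `bin` 0-based
#'   from the window start), `presence` (tibble `signal, frac_present,
#'   present`), `excluded`, `reason`, `missing_frac`.
#' @export
extract_window <- function(minute_series, assess_time,
                           cfg = window_config()) {
  w <- cfg$bin_width_min * 60
  t0 <- as.numeric(assess_time) - cfg$window_start_min * 60
  t1 <- as.numeric(assess_time) - cfg$window_end_min * 60
  first_bin <- ceiling(t0 / w)
  last_bin <- ceiling(t1 / w) - 1          # bins with start in [t0, t1)
  n_bins <- last_bin - first_bin + 1
  sigs <- unique(minute_series$signal)
  grid <- tidyr::expand_grid(signal = sigs, .bin = first_bin:last_bin)
  ms <- dplyr::mutate(minute_series,
                      .bin = floor(as.numeric(.data$bin_start) / w))
  vals <- dplyr::left_join(grid, ms[, c("signal", ".bin", "value")],
                           by = c("signal", ".bin"))
  vals <- dplyr::mutate(vals, bin = .data$.bin - first_bin)
  presence <- vals |>
    dplyr::group_by(.data$signal) |>
    dplyr::summarise(frac_present = mean(!is.na(.data$value)),
                     .groups = "drop") |>
    dplyr::mutate(present = .data$frac_present >= cfg$presence_min_frac)
  missing_frac <- if (nrow(vals) == 0) 1 else mean(is.na(vals$value))
  excluded <- missing_frac > cfg$exclusion_missing_frac
  reason <- if (!excluded) NA_character_ else if (length(sigs) == 0 ||
      all(is.na(vals$value))) {
    "no recorded data in window"
  } else {
    sprintf("all-variable missing fraction %.2f > %.2f",
            missing_frac, cfg$exclusion_missing_frac)
  }
  list(values = tibble::as_tibble(vals[, c("signal", "bin", "value")]),
       presence = presence, excluded = excluded, reason = reason,
       missing_frac = missing_frac, n_bins = n_bins)
}

#' Preprocess a cohort into windowed samples
#'
#' Runs the full preprocessing chain for every assessment of every patient,
#' in the fixed order: resample to minute bins, impute interior gaps per
#' patient and signal, filter clinical-range outliers, then extract the
#' pre-assessment window and apply the presence/exclusion rules. Fully
#' missing signals are never imputed (they are simply absent from the
#' patient's series).
#'
#' @param cohort An `nv_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param cfg An [window_config()].
#' @param ranges Clinical ranges tibble, see [clinical_ranges()].
#' @param impute Logical; set `FALSE` to skip the imputation step.
#' @param k,n_lags,max_gap Imputation parameters, see
#'   [impute_lagged_knn()].
#' @return A list of class `nv_windows`:
#'   \describe{
#'     \item{values}{tibble `sample_id, signal, bin, value`.}
#'     \item{samples}{tibble `sample_id, patient_id, group, time, score,
#'       category, excluded, reason`.}
#'     \item{presence}{tibble `sample_id, signal, frac_present, present`.}
#'     \item{config}{the window configuration.}
#'   }
#' @export
preprocess_cohort <- function(cohort, cfg = window_config(),
                              ranges = clinical_ranges(), impute = TRUE,
                              k = 5, n_lags = 10, max_gap = 10) {
  stopifnot(inherits(cohort, "nv_cohort"))
  ass <- cohort$assessments
  pids <- unique(ass$patient_id)
  values <- list(); samples <- list(); presence <- list()
  sid <- 0L
  for (pid in pids) {
    psig <- cohort$signals[cohort$signals$patient_id == pid, ]
    minute <- psig |>
      dplyr::group_by(.data$signal) |>
      dplyr::group_modify(function(d, key) {
        rs <- resample_bins(d, cfg$bin_width_min, cfg$agg)
        if (impute) {
          rs$value <- impute_lagged_knn(rs$value, k = k, n_lags = n_lags,
                                        max_gap = max_gap)
        }
        rs$value <- filter_outliers(rs$value, key$signal, ranges)
        rs
      }) |>
      dplyr::ungroup()
    pass <- ass[ass$patient_id == pid, ]
    for (a in seq_len(nrow(pass))) {
      sid <- sid + 1L
      sample_id <- sprintf("S%04d", sid)
      win <- extract_window(minute, pass$time[a], cfg)
      samples[[sid]] <- tibble::tibble(
        sample_id = sample_id, patient_id = pid, group = pass$group[a],
        time = pass$time[a], score = pass$score[a],
        category = pass$category[a],
        excluded = win$excluded, reason = win$reason
      )
      if (!win$excluded) {
        values[[sid]] <- dplyr::mutate(win$values, sample_id = sample_id,
                                       .before = 1)
        presence[[sid]] <- dplyr::mutate(win$presence,
                                         sample_id = sample_id, .before = 1)
      }
    }
  }
  structure(list(values = dplyr::bind_rows(values),
                 samples = dplyr::bind_rows(samples),
                 presence = dplyr::bind_rows(presence),
                 config = cfg),
            class = "nv_windows")
}

#' @export
print.nv_windows <- function(x, ...) {
  cat("<nv_windows> ", nrow(x$samples), " assessments (",
      sum(x$samples$excluded), " excluded), ",
      dplyr::n_distinct(x$values$signal), " signals, ",
      x$config$window_start_min - x$config$window_end_min,
      "-min windows\n", sep = "")
  invisible(x)
}
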