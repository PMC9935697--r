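origin_time <- function(s) as.POSIXct(s, tz = "UTC")

test_that("minute resampling averages in-bin samples and flags empty bins", {
  t0 <- origin_time("2020-01-01 10:00:00")
  series <- tibble::tibble(time = t0 + seq(0, 55, by = 5), value = 1:12)
  rs <- resample_bins(series)
  expect_equal(nrow(rs), 1)
  expect_equal(rs$value, 6.5)

  # 15 min of continuous 5-s data -> exactly 15 bins
  series15 <- tibble::tibble(time = t0 + seq(0, 15 * 60 - 5, by = 5),
                             value = rnorm(180))
  expect_equal(nrow(resample_bins(series15)), 15)

  # an interior minute without samples is a missing bin
  gap <- series15[!(series15$time >= t0 + 300 & series15$time < t0 + 360), ]
  rs_gap <- resample_bins(gap)
  expect_equal(nrow(rs_gap), 15)
  expect_true(is.na(rs_gap$value[6]))
  expect_equal(sum(is.na(rs_gap$value)), 1)

  expect_error(resample_bins(tibble::tibble(time = t0 + c(10, 5),
                                            value = 1:2)), "sorted")
})

test_that("outlier filtering is inclusive at the bounds", {
  x <- c(19.9, 20, 100, 220, 220.1, NA)
  y <- filter_outliers(x, "HR")
  expect_equal(y, c(NA, 20, 100, 220, NA, NA))
  ok <- c(60, 80, 100)
  expect_identical(filter_outliers(ok, "HR"), ok)
  expect_error(filter_outliers(1, "XYZ"), "XYZ")
})

test_that("k-NN imputation recovers points of a noiseless sinusoid", {
  n <- 300
  x <- sin(2 * pi * (1:n) / 60)
  x_miss <- x
  hole <- 75  # near the peak, where the relative tolerance is meaningful
  x_miss[hole] <- NA
  y <- impute_lagged_knn(x_miss, k = 5, n_lags = 10)
  expect_false(is.na(y[hole]))
  expect_lt(abs(y[hole] - x[hole]) / abs(x[hole]), 0.05)
})

test_that("imputation never alters observed values", {
  set.seed(11)
  x <- as.numeric(arima.sim(list(ar = 0.8), 400)) + 10
  x[sample(50:350, 20)] <- NA
  obs <- !is.na(x)
  y <- impute_lagged_knn(x)
  expect_identical(y[obs], x[obs])
  # re-mask 10% of observed points: only those may change
  set.seed(12)
  mask <- sample(which(obs)[50:250], 30)
  x2 <- x; x2[mask] <- NA
  y2 <- impute_lagged_knn(x2)
  expect_identical(y2[!is.na(x2)], x[!is.na(x2)])
})

test_that("imputation edge cases: pass-through and parameter checks", {
  expect_error(impute_lagged_knn(rnorm(10), k = 0), "k")
  x <- rnorm(100)
  expect_identical(impute_lagged_knn(x), x)          # nothing missing
  allna <- rep(NA_real_, 100)
  expect_identical(impute_lagged_knn(allna), allna)  # fully missing
  few <- c(1, NA, 2, rep(NA, 50))
  expect_identical(impute_lagged_knn(few, k = 5), few)  # < k observed
  # gaps longer than max_gap stay missing
  z <- sin(2 * pi * (1:200) / 40)
  z[80:120] <- NA
  z2 <- impute_lagged_knn(z, max_gap = 10)
  expect_true(all(is.na(z2[80:120])))
})

test_that("window spans the 140 minutes from t-200 to t-60 exclusively", {
  ms <- make_minute_series("HR", origin_time("2020-01-01 04:00:00"),
                           origin_time("2020-01-01 09:00:00"))
  win <- extract_window(ms, origin_time("2020-01-01 09:00:00"))
  expect_equal(win$n_bins, 140)
  hr <- win$values[win$values$signal == "HR", ]
  expect_equal(nrow(hr), 140)
  # values were the 1-based bin index from 04:00, so 05:40 -> index 101
  expect_equal(hr$value[hr$bin == 0], 101)
  expect_equal(hr$value[hr$bin == 139], 240)  # bin starting 07:59
  expect_false(win$excluded)
})

test_that("presence mask follows the 80% rule per signal", {
  from <- origin_time("2020-01-01 04:00:00")
  ms <- make_minute_series(c("HR", "RR"), from,
                           origin_time("2020-01-01 09:00:00"))
  # HR present 79% of the window, RR 95%
  idx_hr <- ms$signal == "HR"
  win_bins <- ms$bin_start >= origin_time("2020-01-01 05:40:00") &
    ms$bin_start < origin_time("2020-01-01 08:00:00")
  hr_bins <- which(idx_hr & win_bins)
  rr_bins <- which(!idx_hr & win_bins)
  ms$value[hr_bins[1:(140 - floor(0.79 * 140))]] <- NA
  ms$value[rr_bins[1:(140 - ceiling(0.95 * 140))]] <- NA
  win <- extract_window(ms, origin_time("2020-01-01 09:00:00"))
  p <- win$presence
  expect_false(p$present[p$signal == "HR"])
  expect_true(p$present[p$signal == "RR"])
})

test_that("assessments with >80% all-variable missingness are excluded", {
  from <- origin_time("2020-01-01 04:00:00")
  ms <- make_minute_series(c("HR", "RR"), from,
                           origin_time("2020-01-01 09:00:00"))
  n <- nrow(ms)
  set.seed(5)
  ms$value[sample(n, round(0.9 * n))] <- NA
  win <- extract_window(ms, origin_time("2020-01-01 09:00:00"))
  expect_true(win$excluded)
  expect_match(win$reason, "missing")
  # an assessment before any recorded data is excluded, not an error
  early <- extract_window(ms, origin_time("2019-12-25 09:00:00"))
  expect_true(early$excluded)
})

test_that("exclusion and presence agree with a brute-force recount", {
  set.seed(21)
  for (rep in 1:10) {
    from <- origin_time("2020-01-01 00:00:00")
    ms <- make_minute_series(c("HR", "MAP"), from,
                             origin_time("2020-01-01 06:00:00"),
                             value_fn = function(b) rnorm(length(b)))
    ms$value[runif(nrow(ms)) < runif(1, 0.5, 0.95)] <- NA
    t_assess <- origin_time("2020-01-01 05:30:00")
    cfg <- window_config(window_start_min = 60, window_end_min = 20)
    win <- extract_window(ms, t_assess, cfg)
    lo <- as.numeric(t_assess) - 3600; hi <- as.numeric(t_assess) - 1200
    in_win <- as.numeric(ms$bin_start) >= lo & as.numeric(ms$bin_start) < hi
    for (sg in c("HR", "MAP")) {
      sel <- in_win & ms$signal == sg
      frac <- sum(!is.na(ms$value[sel])) / 40
      expect_equal(win$presence$frac_present[win$presence$signal == sg],
                   frac)
      expect_equal(win$presence$present[win$presence$signal == sg],
                   frac >= 0.8)
    }
    pooled_missing <- mean(is.na(ms$value[in_win]))
    expect_equal(win$excluded, pooled_missing > 0.8)
  }
})

test_that("window extraction is invariant to a common time shift", {
  set.seed(31)
  ms <- make_minute_series(c("HR", "RR"), origin_time("2020-01-01 04:00:00"),
                           origin_time("2020-01-01 09:00:00"),
                           value_fn = function(b) rnorm(length(b)))
  ms$value[sample(nrow(ms), 60)] <- NA
  t1 <- origin_time("2020-01-01 08:47:00") + 23  # not minute-aligned
  w1 <- extract_window(ms, t1)
  shift <- 37 * 3600 + 25 * 60  # whole minutes
  ms2 <- dplyr::mutate(ms, bin_start = bin_start + shift)
  w2 <- extract_window(ms2, t1 + shift)
  expect_equal(w1$values$value, w2$values$value)
  expect_equal(w1$presence$frac_present, w2$presence$frac_present)
  expect_equal(w1$excluded, w2$excluded)
})

test_that("cohort preprocessing yields one row per assessment", {
  coh <- generate_cohort(cohort_config(n_patients = 3,
                                       signals = c("HR", "RR"),
                                       assessments_mean = 3,
                                       assessments_sd = 1, seed = 8))
  win <- preprocess_cohort(coh)
  expect_equal(nrow(win$samples), nrow(coh$assessments))
  kept <- win$samples$sample_id[!win$samples$excluded]
  expect_true(all(win$values$sample_id %in% kept))
  expect_true(all(win$values$bin %in% 0:139))
  per_sig <- dplyr::count(win$values, sample_id, signal)
  expect_true(all(per_sig$n == 140))
})

test_that("window configuration is validated", {
  expect_error(window_config(window_start_min = 60, window_end_min = 60))
  expect_error(window_config(exclusion_missing_frac = 0))
  expect_silent(window_config(window_start_min = 120, window_end_min = 0))
})
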