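#' Configuration for a synthetic neuro-ICU cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' Defaults emulate the structure of a hemorrhagic-stroke neuro-ICU
#' population: per-group assessment counts (SAH: 4.38 +/- 2.86, ICH:
#' 8.6 +/- 2.89 assessments per patient), daily morning assessments between
#' 08:00 and 11:00, 5-second signal sampling during a morning monitoring
#' block, per-signal whole-signal absence rates that differ sharply between
#' the SAH and ICH groups, and within-signal gap missingness.
#'
#' @param n_patients Number of patients (>= 2).
#' @param group Patient group, `"SAH"` or `"ICH"`; picks the default
#'   assessment-count distribution and absence probabilities.
#' @param assessments_mean,assessments_sd Mean and SD of the per-patient
#'   assessment count (one assessment per ICU day); defaults depend on
#'   `group`.
#' @param signal_absence_prob Named numeric vector: probability that each
#'   signal is never recorded for a patient. Defaults to
#'   [default_absence_probs()] for the group.
#' @param gap_rate Expected fraction of in-series samples lost to
#'   contiguous gaps (structured instance missingness).
#' @param gap_mean_len Mean gap length in samples for the default geometric
#'   gap-length distribution.
#' @param effect_size Scalar >= 0 controlling how strongly the consciousness
#'   state modulates signal variability/complexity; 0 gives a null cohort in
#'   which signals carry no information about state.
#' @param persistence Probability that the day-to-day first-order Markov
#'   chain over behavioral scores stays in the current score.
#' @param signals Signals to simulate (subset of [signal_names()]).
#' @param record_start_hour Hour of day at which the daily monitoring block
#'   starts (default 4.5, i.e. 04:30, so the pre-assessment window is always
#'   covered).
#' @param record_duration_s Length of the daily monitoring block in seconds.
#' @param seed Integer seed; fixed seed gives a bit-identical cohort.
#' @return A list of class `nv_cohort_config`.
#' @export
cohort_config <- function(n_patients = 20,
                          group = c("SAH", "ICH"),
                          assessments_mean = NULL,
                          assessments_sd = NULL,
                          signal_absence_prob = NULL,
                          gap_rate = 0.05,
                          gap_mean_len = 24,
                          effect_size = 1,
                          persistence = 0.6,
                          signals = signal_names(),
                          record_start_hour = 4.5,
                          record_duration_s = 7 * 3600,
                          seed = 1L) {
  group <- match.arg(group)
  if (is.null(assessments_mean)) {
    assessments_mean <- if (group == "SAH") 4.38 else 8.6
  }
  if (is.null(assessments_sd)) {
    assessments_sd <- if (group == "SAH") 2.86 else 2.89
  }
  if (is.null(signal_absence_prob)) {
    signal_absence_prob <- default_absence_probs(group)
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 2) {
    stop("`n_patients` must be a single number >= 2", call. = FALSE)
  }
  stopifnot(all(signals %in% signal_names()))
  bad <- signal_absence_prob < 0 | signal_absence_prob > 1
  if (any(is.na(signal_absence_prob)) || any(bad)) {
    stop("`signal_absence_prob` entries must be probabilities in [0, 1]",
         call. = FALSE)
  }
  if (gap_rate < 0 || gap_rate > 1) {
    stop("`gap_rate` must be in [0, 1]", call. = FALSE)
  }
  if (effect_size < 0) stop("`effect_size` must be >= 0", call. = FALSE)
  if (persistence < 0 || persistence > 1) {
    stop("`persistence` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients), group = group,
      assessments_mean = assessments_mean, assessments_sd = assessments_sd,
      signal_absence_prob = signal_absence_prob,
      gap_rate = gap_rate, gap_mean_len = gap_mean_len,
      effect_size = effect_size, persistence = persistence,
      signals = signals,
      record_start_hour = record_start_hour,
      record_duration_s = record_duration_s,
      seed = as.integer(seed)
    ),
    class = "nv_cohort_config"
  )
}

#' Map a behavioral score to its per-state variability multiplier
#'
#' The innovation standard deviation of a simulated signal is scaled by
#' `1 + effect_size * score / 5`, so deeper unconsciousness (lower score)
#' yields lower short-term variability and lower complexity, in line with
#' the reduced heart-rate variability observed in deepening coma. With
#' `effect_size = 0` the multiplier is 1 for every score (null model).
#'
#' @param effect_size Scalar >= 0.
#' @return Numeric vector of length 6 (scores 0 to 5).
#' @export
state_effect_multipliers <- function(effect_size = 1) {
  1 + effect_size * (0:5) / 5
}

#' Simulate a day-to-day behavioral score trajectory
#'
#' First-order Markov chain over scores 0--5: stay with probability
#' `persistence`, otherwise step to an adjacent score (reflecting at the
#' boundaries). The initial score is uniform over 0--5.
#'
#' @param n_days Number of ICU days (one score per day).
#' @param persistence Stay probability in `[0, 1]`.
#' @return Integer vector of length `n_days` with values in 0--5.
#' @export
simulate_trajectory <- function(n_days, persistence = 0.6) {
  stopifnot(n_days >= 1)
  s <- integer(n_days)
  s[1] <- sample(0:5, 1)
  if (n_days > 1) {
    for (d in 2:n_days) {
      prev <- s[d - 1]
      if (stats::runif(1) < persistence) {
        s[d] <- prev
      } else {
        steps <- c(-1, 1)
        steps <- steps[prev + steps >= 0 & prev + steps <= 5]
        s[d] <- prev + sample(steps, 1)
      }
    }
  }
  s
}

#' Simulate one physiological signal across a patient's stay
#'
#' Generates a discretized mean-reverting (Ornstein--Uhlenbeck) process
#' around the signal's baseline, plus a slow periodic component, sampled
#' every `sampling_period` seconds in a daily monitoring block of
#' `duration_s` seconds. The per-day behavioral score scales the innovation
#' standard deviation via [state_effect_multipliers()], so both the
#' short-term variability and the sample entropy of the series increase
#' with the score when `effect_size > 0` and are state-independent when
#' `effect_size = 0`.
#'
#' @param scores Integer vector of per-day behavioral scores (0--5); its
#'   length sets the number of days.
#' @param spec One row of [signal_specs()] (or a compatible list) with
#'   `baseline_mean`, `noise_sd`, `period_min`, `sampling_period`.
#' @param duration_s Seconds recorded per day (>= 0; 0 gives an empty
#'   series).
#' @param effect_size Scalar >= 0; see [cohort_config()].
#' @param state_effect Optional numeric vector of length 6 overriding the
#'   default per-score multipliers.
#' @param theta Mean-reversion rate per sampling step.
#' @param seed Optional integer seed (set only if non-NULL).
#' @return Tibble with columns `day`, `t_s` (seconds since the start of the
#'   day's block), `score`, `value`.
#' @export
simulate_signal <- function(scores, spec, duration_s = 7 * 3600,
                            effect_size = 1, state_effect = NULL,
                            theta = 0.05, seed = NULL) {
  if (duration_s < 0) stop("`duration_s` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(scores %in% 0:5))
  if (is.null(state_effect)) state_effect <- state_effect_multipliers(effect_size)
  stopifnot(length(state_effect) == 6)
  dt <- spec$sampling_period
  n_per_day <- floor(duration_s / dt)
  if (n_per_day == 0) {
    return(tibble::tibble(day = integer(), t_s = numeric(),
                          score = integer(), value = numeric()))
  }
  n_days <- length(scores)
  day <- rep(seq_len(n_days), each = n_per_day)
  t_s <- rep(seq(0, by = dt, length.out = n_per_day), times = n_days)
  sigma <- spec$noise_sd * state_effect[scores[day] + 1]
  eps <- stats::rnorm(n_days * n_per_day, 0, sigma)
  # AR(1) recursion x_t = (1 - theta) x_{t-1} + eps_t around the baseline
  x <- as.numeric(stats::filter(eps, 1 - theta, method = "recursive"))
  amp <- spec$noise_sd * state_effect[scores[day] + 1]
  periodic <- amp * sin(2 * pi * t_s / (spec$period_min * 60))
  tibble::tibble(
    day = day, t_s = t_s, score = scores[day],
    value = spec$baseline_mean + x + periodic
  )
}

#' Inject contiguous gaps of missing values into a series
#'
#' Marks contiguous runs of a numeric vector as `NA` so that the realized
#' missing fraction equals `round(length(x) * gap_rate) / length(x)`. Run
#' lengths are drawn from `gap_length_dist` (default: geometric with mean
#' `gap_mean_len`); run start positions are uniform. Non-gap values are
#' returned unchanged.
#'
#' @param x Numeric vector.
#' @param gap_rate Target missing fraction in `[0, 1]`.
#' @param gap_length_dist Function `n -> n` positive integer run lengths.
#' @param gap_mean_len Mean of the default geometric run-length
#'   distribution.
#' @param seed Optional integer seed.
#' @return `x` with gap positions set to `NA`.
#' @export
inject_missingness <- function(x, gap_rate, gap_length_dist = NULL,
                               gap_mean_len = 24, seed = NULL) {
  if (gap_rate < 0 || gap_rate > 1) {
    stop("`gap_rate` must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  if (n == 0 || gap_rate == 0) return(x)
  if (gap_rate == 1) return(rep(NA_real_, n))
  if (is.null(gap_length_dist)) {
    gap_length_dist <- function(k) 1L + stats::rgeom(k, 1 / gap_mean_len)
  }
  target <- round(n * gap_rate)
  if (target == 0) return(x)
  miss <- logical(n)
  while (sum(miss) < target) {
    len <- max(1L, gap_length_dist(1L))
    start <- sample.int(n, 1)
    idx <- start:min(n, start + len - 1L)
    new <- idx[!miss[idx]]
    excess <- (sum(miss) + length(new)) - target
    if (excess > 0) new <- new[seq_len(length(new) - excess)]
    miss[new] <- TRUE
  }
  x[miss] <- NA_real_
  x
}

#' Generate a synthetic neuro-ICU cohort
#'
#' Produces a cohort of synthetic patients with the data structure the
#' downstream pipeline assumes: per-patient daily behavioral assessments
#' (scores 0--5, performed between 08:00 and 11:00), multi-signal raw series
#' sampled every 5 s during a daily morning monitoring block, whole-signal
#' absence with the configured per-signal probabilities, and contiguous
#' within-signal gaps. The cohort is bit-identical for a fixed seed.
#'
#' @param cfg An [cohort_config()] object.
#' @return A list of class `nv_cohort` with elements
#'   \describe{
#'     \item{signals}{tibble `patient_id, group, signal, time, value` (long
#'       format, missing instances absent).}
#'     \item{assessments}{tibble `patient_id, group, time, score, category`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 3, signals = "HR",
#'                                      seed = 7))
#' dplyr::count(coh$assessments, patient_id)
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "nv_cohort_config"))
  set.seed(cfg$seed)
  specs <- signal_specs()
  origin <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  all_sig <- vector("list", cfg$n_patients)
  all_ass <- vector("list", cfg$n_patients)
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%03d", p)
    n_days <- max(1L, as.integer(round(
      stats::rnorm(1, cfg$assessments_mean, cfg$assessments_sd))))
    scores <- simulate_trajectory(n_days, cfg$persistence)
    assess_time <- origin + (seq_len(n_days) - 1) * 86400 +
      8 * 3600 + stats::runif(n_days, 0, 3 * 3600)
    all_ass[[p]] <- tibble::tibble(
      patient_id = pid, group = cfg$group, time = assess_time,
      score = scores, category = map_score_to_category(scores)
    )
    absent <- stats::runif(length(cfg$signals)) <
      cfg$signal_absence_prob[cfg$signals]
    recorded <- cfg$signals[!absent]
    sig_list <- lapply(recorded, function(sg) {
      spec <- specs[specs$signal == sg, ]
      raw <- simulate_signal(scores, spec, cfg$record_duration_s,
                             effect_size = cfg$effect_size)
      raw$value <- inject_missingness(raw$value, cfg$gap_rate,
                                      gap_mean_len = cfg$gap_mean_len)
      raw <- raw[!is.na(raw$value), ]
      tibble::tibble(
        patient_id = pid, group = cfg$group, signal = sg,
        time = origin + (raw$day - 1) * 86400 +
          cfg$record_start_hour * 3600 + raw$t_s,
        value = raw$value
      )
    })
    all_sig[[p]] <- dplyr::bind_rows(sig_list)
  }
  structure(
    list(signals = dplyr::bind_rows(all_sig),
         assessments = dplyr::bind_rows(all_ass),
         config = cfg),
    class = "nv_cohort"
  )
}

#' @export
print.nv_cohort <- function(x, ...) {
  cat("<nv_cohort> ", x$config$group, " group: ",
      dplyr::n_distinct(x$assessments$patient_id), " patients, ",
      nrow(x$assessments), " assessments, ",
      nrow(x$signals), " signal samples\n", sep = "")
  invisible(x)
}

#' Write / read a cohort in the canonical long CSV format
#'
#' The pipeline's canonical on-disk input format is a pair of CSVs: a long
#' signal table `patient_id, group, signal, time, value` (ISO-8601 UTC
#' timestamps) and an assessment table `patient_id, group, time, score`.
#'
#' @param cohort An `nv_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` an
#'   `nv_cohort` (without a generating config).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- dplyr::mutate(cohort$signals,
                       time = format(.data$time, "%Y-%m-%dT%H:%M:%S",
                                     tz = "UTC"))
  ass <- dplyr::mutate(cohort$assessments,
                       time = format(.data$time, "%Y-%m-%dT%H:%M:%S",
                                     tz = "UTC"))
  readr::write_csv(sig, file.path(dir, "signals.csv"))
  readr::write_csv(ass[, c("patient_id", "group", "time", "score")],
                   file.path(dir, "assessments.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  sig <- readr::read_csv(file.path(dir, "signals.csv"),
                         show_col_types = FALSE)
  ass <- readr::read_csv(file.path(dir, "assessments.csv"),
                         show_col_types = FALSE)
  sig$time <- as.POSIXct(sig$time, tz = "UTC",
                         format = "%Y-%m-%dT%H:%M:%S")
  ass$time <- as.POSIXct(ass$time, tz = "UTC",
                         format = "%Y-%m-%dT%H:%M:%S")
  ass$category <- map_score_to_category(ass$score)
  structure(list(signals = tibble::as_tibble(sig),
                 assessments = tibble::as_tibble(ass),
                 config = NULL),
    class = "nv_cohort"
  )
}
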