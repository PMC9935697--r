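# Shared in-code fixtures.

# Hand-built cross-validation result: `spec` is a list of rounds, each a
# list(signals = features used per signal, top = ordered importance values).
make_cv <- function(rounds) {
  structure(list(
    predictions = tibble::tibble(),
    rounds = rounds,
    skipped = tibble::tibble(),
    config = NULL
  ), class = "nv_cv")
}

# One round with given feature names (named gain vector, already a ranking).
make_round <- function(patient_id, gains) {
  list(patient_id = patient_id,
       signals_used = unique(sub("__.*$", "", names(gains))),
       features_used = names(gains),
       params = list(), nrounds = 10,
       importance = tibble::tibble(feature = names(gains),
                                   gain = unname(gains)))
}

# Small minute-series table for window-extraction tests: one patient,
# complete minute grid over [from, to) with given values per signal.
make_minute_series <- function(signals, from, to, value_fn = function(b) b) {
  grid <- seq(as.numeric(from), as.numeric(to) - 60, by = 60)
  dplyr::bind_rows(lapply(signals, function(sg) {
    tibble::tibble(signal = sg,
                   bin_start = as.POSIXct(grid, origin = "1970-01-01",
                                          tz = "UTC"),
                   value = value_fn(seq_along(grid)))
  }))
}

# Labeled synthetic feature dataset with controllable per-patient signal
# missingness; `informative` adds a label-correlated HR feature.
make_task_dataset <- function(n_patients = 8, per_patient = 3,
                              signals = c("HR", "MAP"),
                              drop_signal = list(), seed = 1,
                              informative = TRUE) {
  set.seed(seed)
  feats <- paste0("f", 1:4)
  rows <- list()
  sid <- 0
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    for (s in seq_len(per_patient)) {
      sid <- sid + 1
      label <- rbinom(1, 1, 0.5)
      row <- list(sample_id = sprintf("S%04d", sid), patient_id = pid,
                  label = label)
      for (sg in signals) {
        absent <- sg %in% (drop_signal[[pid]] %||% character(0))
        for (f in feats) {
          v <- if (absent) NA_real_ else rnorm(1)
          if (!absent && informative && sg == "HR" && f == "f1") {
            v <- v + 3 * label
          }
          row[[paste(sg, f, sep = "__")]] <- v
        }
      }
      rows[[sid]] <- tibble::as_tibble(row)
    }
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reduced tuning configuration used for pipeline-scale tests.
small_model_config <- function(seed = 1) {
  model_config(grid = list(gamma = 0, min_child_weight = c(1, 5),
                           max_depth = c(2, 4), learning_rate = 0.1),
               n_estimators = 60, inner_folds = 3, seed = seed)
}
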