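#' Physiological signals known to the pipeline
#'
#' The nine continuously recorded neuro-ICU signals handled by the pipeline:
#' heart rate (HR), respiratory rate (RR), oxygen saturation (SPO2),
#' mean arterial pressure (MAP), body temperature (TMP), end-tidal CO2
#' (CO2EX), intracranial pressure (ICP), brain tissue oxygenation (PbtO2)
#' and brain temperature (BrT).
#'
#' @return Character vector of the nine canonical signal names.
#' @export
signal_names <- function() {
  c("HR", "RR", "SPO2", "MAP", "TMP", "CO2EX", "ICP", "PbtO2", "BrT")
}

#' Default per-signal simulation parameters
#'
#' One row per signal: baseline mean and short-term noise in physical units,
#' the period (minutes) of the slow quasi-periodic component, and the native
#' sampling period in seconds. These drive the mean-reverting
#' (Ornstein--Uhlenbeck) signal simulator; consciousness-state dependence is
#' applied on top as a multiplier on the innovation standard deviation (see
#' [simulate_signal()]).
#'
#' @return Tibble with columns `signal`, `baseline_mean`, `noise_sd`,
#'   `period_min`, `sampling_period`.
#' @export
signal_specs <- function() {
  tibble::tribble(
    ~signal, ~baseline_mean, ~noise_sd, ~period_min, ~sampling_period,
    "HR",     80,   2.0,  5,  5,
    "RR",     18,   1.2,  4,  5,
    "SPO2",   97,   0.5,  8,  5,
    "MAP",    90,   3.0,  6,  5,
    "TMP",    37,   0.05, 30, 5,
    "CO2EX",  38,   1.5,  4,  5,
    "ICP",    12,   1.5,  5,  5,
    "PbtO2",  25,   1.5,  8,  5,
    "BrT",    37.2, 0.05, 30, 5
  )
}

#' Default clinically plausible ranges used for outlier filtering
#'
#' Values outside these inclusive ranges are treated as sensor artefacts and
#' set to missing by [filter_outliers()]. All ranges are configurable; these
#' defaults are deliberately permissive so that only physically impossible
#' readings are removed.
#'
#' @return Tibble with columns `signal`, `lower`, `upper` (physical units).
#' @export
clinical_ranges <- function() {
  tibble::tribble(
    ~signal, ~lower, ~upper,
    "HR",     20, 220,
    "RR",      2,  60,
    "SPO2",   50, 100,
    "MAP",    20, 200,
    "TMP",    30,  43,
    "CO2EX",   5, 100,
    "ICP",    -5, 100,
    "PbtO2",   0, 150,
    "BrT",    30,  43
  )
}

#' Variable subsets by care setting
#'
#' Nested subsets of signals mirroring where each variable is routinely
#' recorded: `hospital` (HR, RR, SPO2) for most hospital patients, `icu`
#' adds MAP, TMP and CO2EX, and `neuro` further adds the invasive
#' neuro-monitoring signals ICP, PbtO2 and BrT. The subsets are nested:
#' hospital < icu < neuro.
#'
#' @param subset One of `"hospital"`, `"icu"`, `"neuro"`.
#' @return Character vector of signal names in the subset.
#' @export
#' @examples
#' variable_subset("hospital")
variable_subset <- function(subset = c("hospital", "icu", "neuro")) {
  subset <- match.arg(subset)
  hospital <- c("HR", "RR", "SPO2")
  icu <- c(hospital, "MAP", "TMP", "CO2EX")
  neuro <- c(icu, "ICP", "PbtO2", "BrT")
  switch(subset, hospital = hospital, icu = icu, neuro = neuro)
}

#' Default per-signal whole-signal absence probabilities
#'
#' Probability that a signal is never recorded for a patient, by patient
#' group (SAH = aneurysmal subarachnoid hemorrhage, ICH = intracerebral
#' hemorrhage). SAH patients in this setting undergo invasive brain
#' monitoring far more often, so ICP-type signals are rarely absent for
#' them but almost always absent for ICH patients. Signals without a
#' documented rate default to 0.2.
#'
#' @param group `"SAH"` or `"ICH"`.
#' @return Named numeric vector over [signal_names()].
#' @export
default_absence_probs <- function(group = c("SAH", "ICH")) {
  group <- match.arg(group)
  p <- stats::setNames(rep(0.2, 9), signal_names())
  if (group == "SAH") {
    p[c("HR", "SPO2", "TMP", "ICP")] <- c(0.01, 0.07, 0.43, 0.07)
    p[c("PbtO2", "BrT")] <- 0.2
  } else {
    p[c("HR", "SPO2", "TMP", "ICP")] <- c(0.00, 0.03, 0.74, 0.88)
    p[c("PbtO2", "BrT")] <- 0.95
  }
  p
}
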