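#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the ROC curve of an evaluation
#'
#' @param object An `nv_eval` from [evaluate_cv()].
#' @param ... Unused.
#' @return A ggplot: ROC curve with the chance diagonal and the operating
#'   point marked.
#' @exportS3Method ggplot2::autoplot
autoplot.nv_eval <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, shape = 4, size = 3,
                      colour = "#d95f02") +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("ROC curve (AUROC %.2f, 95%% CI %.2f-%.2f)",
                      object$auroc, object$ci_low, object$ci_high)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot the LOWESS calibration curve of an evaluation
#'
#' @param eval An `nv_eval` with a non-`NULL` calibration component.
#' @return A ggplot of smoothed observed versus predicted probability.
#' @export
plot_calibration <- function(eval) {
  stopifnot(inherits(eval, "nv_eval"))
  if (is.null(eval$calibration)) {
    stop("no calibration component (fewer than 20 pooled samples)",
         call. = FALSE)
  }
  cv <- dplyr::arrange(eval$calibration$curve, .data$prob)
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$prob, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "predicted probability",
                  y = "observed probability (LOWESS)",
                  title = sprintf("Calibration (ICI %.3f, Emax %.3f)",
                                  eval$calibration$ici,
                                  eval$calibration$emax)) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-signal relevance
#'
#' @param eval An `nv_eval`.
#' @return A ggplot of signal relevance (share of LOPO rounds in the top-k
#'   importances among rounds where the signal was used).
#' @export
plot_relevance <- function(eval) {
  stopifnot(inherits(eval, "nv_eval"))
  rel <- eval$relevance
  ggplot2::ggplot(rel, ggplot2::aes(
    x = stats::reorder(.data$signal, .data$relevance),
    y = .data$relevance)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "signal relevance") +
    ggplot2::theme_minimal()
}

#' Plot raw signal traces for one synthetic patient
#'
#' @param object An `nv_cohort`.
#' @param patient_id Patient to show (default: first).
#' @param ... Unused.
#' @return A ggplot with one facet per recorded signal; assessment times
#'   are marked with vertical lines.
#' @exportS3Method ggplot2::autoplot
autoplot.nv_cohort <- function(object, patient_id = NULL, ...) {
  if (is.null(patient_id)) patient_id <- object$signals$patient_id[1]
  sig <- object$signals[object$signals$patient_id == patient_id, ]
  ass <- object$assessments[object$assessments$patient_id == patient_id, ]
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "#2c7fb8") +
    ggplot2::geom_vline(data = ass,
                        ggplot2::aes(xintercept = .data$time),
                        linetype = "dotted", colour = "#d95f02") +
    ggplot2::facet_wrap(~signal, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Synthetic signals,", patient_id)) +
    ggplot2::theme_minimal()
}
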