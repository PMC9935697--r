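#' ROC curve and AUROC
#'
#' The AUROC is computed as the probability that a randomly chosen
#' positive sample receives a higher probability than a randomly chosen
#' negative one, with ties counted one half (midrank / Mann-Whitney
#' statistic). The returned curve contains one point per distinct
#' threshold (predict positive when `prob >= threshold`), and its
#' trapezoidal area equals the rank-based AUROC.
#'
#' @param labels Binary 0/1 vector.
#' @param probs Predicted probabilities (or any scores).
#' @return List with `curve` (tibble `threshold, sensitivity,
#'   specificity`) and `auroc`.
#' @export
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auroc  # 0.75
roc_auc <- function(labels, probs) {
  stopifnot(length(labels) == length(probs))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an ROC curve",
         call. = FALSE)
  }
  rk <- rank(probs)               # midranks handle ties as 1/2
  auroc <- (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(probs >= t & labels == 1) / n1,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(probs < t & labels == 0) / n0,
                 numeric(1))
  list(curve = tibble::tibble(threshold = thr, sensitivity = sens,
                              specificity = spec),
       auroc = auroc)
}

#' DeLong 95% confidence interval for the AUROC
#'
#' Asymptotic confidence interval based on the DeLong covariance of
#' placement values, truncated to `[0, 1]`. When the classes are perfectly
#' separated the placement-value variance is zero and the degenerate
#' interval `[auroc, auroc]` is returned with a warning.
#'
#' @param labels Binary 0/1 vector (>= 2 samples per class).
#' @param probs Predicted probabilities.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
delong_ci <- function(labels, probs, level = 0.95) {
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  auc <- roc_auc(labels, probs)$auroc
  if (auc %in% c(0, 1)) {
    warning("perfect separation: degenerate DeLong interval")
    return(c(auc, auc))
  }
  r <- suppressMessages(pROC::roc(labels, probs, quiet = TRUE,
                                  direction = "<", levels = c(0, 1)))
  ci <- suppressWarnings(as.numeric(
    pROC::ci.auc(r, method = "delong", conf.level = level)))
  c(max(0, ci[1]), min(1, ci[3]))
}

#' Operating point of an ROC curve (Youden's J)
#'
#' Picks the threshold maximizing `J = sensitivity + specificity - 1`,
#' breaking ties towards higher sensitivity and then lower threshold. The
#' closest-to-(0,1) criterion is available via `criterion =
#' "closest01"`; the two coincide on symmetric curves.
#'
#' @param curve Tibble `threshold, sensitivity, specificity` from
#'   [roc_auc()].
#' @param criterion `"youden"` (default) or `"closest01"`.
#' @return List `sensitivity, specificity, threshold`.
#' @export
operating_point <- function(curve, criterion = c("youden", "closest01")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(curve) > 0)
  score <- if (criterion == "youden") {
    curve$sensitivity + curve$specificity - 1
  } else {
    -sqrt((1 - curve$sensitivity)^2 + (1 - curve$specificity)^2)
  }
  ord <- order(-score, -curve$sensitivity, curve$threshold)
  i <- ord[1]
  list(sensitivity = curve$sensitivity[i],
       specificity = curve$specificity[i],
       threshold = curve$threshold[i])
}

#' AUPRC with its no-skill baseline
#'
#' Area under the precision--recall curve by step-wise integration
#' (average precision over distinct thresholds); the no-skill baseline is
#' the prevalence of the positive class, which under the minority-positive
#' labeling convention equals minority-class prevalence.
#'
#' @param labels Binary 0/1 vector.
#' @param probs Predicted probabilities.
#' @return List `auprc, baseline`.
#' @export
auprc_with_baseline <- function(labels, probs) {
  n1 <- sum(labels == 1); n <- length(labels)
  if (n1 == 0 || n1 == n) {
    stop("both classes must be present", call. = FALSE)
  }
  thr <- sort(unique(probs), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(probs >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(probs >= t & labels == 0), numeric(1))
  recall <- c(0, tp / n1)
  precision <- c(1, tp / (tp + fp))
  auprc <- sum(diff(recall) * precision[-1])
  list(auprc = auprc, baseline = n1 / n)
}

#' Confusion matrix and accuracy at a threshold
#'
#' @param labels Binary 0/1 vector.
#' @param probs Predicted probabilities.
#' @param threshold Decision threshold (predict positive when
#'   `prob >= threshold`).
#' @return List `matrix` (2x2, rows = truth, cols = prediction) and
#'   `accuracy`.
#' @export
confusion_accuracy <- function(labels, probs, threshold) {
  stopifnot(is.finite(threshold) || is.infinite(threshold))
  pred <- as.integer(probs >= threshold)
  m <- matrix(c(sum(labels == 0 & pred == 0), sum(labels == 0 & pred == 1),
                sum(labels == 1 & pred == 0), sum(labels == 1 & pred == 1)),
              nrow = 2, byrow = TRUE,
              dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  list(matrix = m, accuracy = sum(diag(m)) / length(labels))
}

#' LOWESS calibration curve, ICI and Emax
#'
#' Estimates the observed event probability as a locally weighted
#' regression (LOWESS, span `f`) of the binary outcomes on the predicted
#' probabilities, clamped to `[0, 1]`. The integrated calibration index
#' (ICI) is the mean absolute difference between the smoothed observed and
#' the predicted probability over the samples; Emax is the maximum
#' absolute difference.
#'
#' @param labels Binary 0/1 vector of length >= 20.
#' @param probs Predicted probabilities.
#' @param f LOWESS span (default 0.75).
#' @return List `curve` (tibble `prob, observed`), `ici`, `emax`.
#' @export
calibration_report <- function(labels, probs, f = 0.75) {
  n <- length(labels)
  if (n < 20) {
    stop("calibration assessment needs at least 20 samples (got ", n, ")",
         call. = FALSE)
  }
  lo <- stats::lowess(probs, labels, f = f, iter = 0)
  sm <- stats::approx(lo$x, lo$y, xout = probs, rule = 2, ties = mean)$y
  sm <- pmin(1, pmax(0, sm))
  err <- abs(sm - probs)
  list(curve = tibble::tibble(prob = probs, observed = sm),
       ici = mean(err), emax = max(err))
}

#' Per-signal relevance from LOPO feature importances
#'
#' For each LOPO round, features are ranked by importance and the top `k`
#' taken; each signal with at least one feature in the top `k` counts once
#' for that round, regardless of how many of its features appear. A
#' signal's relevance is the number of rounds it reached the top `k`
#' divided by the number of rounds in which it was used for training at
#' all. Signals never used in any round have an undefined ratio and are
#' excluded from the table.
#'
#' @param cv An `nv_cv` from [lopo_cv()] (needs per-round importances).
#' @param k Number of top features per round (default 5).
#' @return Tibble `signal, times_in_topk, times_used, relevance`, sorted
#'   by decreasing relevance.
#' @export
signal_relevance <- function(cv, k = 5) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  stopifnot(inherits(cv, "nv_cv"))
  used <- list(); topk <- list()
  for (rd in cv$rounds) {
    used_sigs <- unique(signal_of_column(rd$features_used))
    imp <- rd$importance
    top_sigs <- character(0)
    if (!is.null(imp) && nrow(imp) > 0) {
      top <- imp$feature[order(-imp$gain)][seq_len(min(k, nrow(imp)))]
      top_sigs <- unique(signal_of_column(top))
    }
    used[[length(used) + 1]] <- used_sigs
    topk[[length(topk) + 1]] <- top_sigs
  }
  all_used <- unlist(used)
  if (length(all_used) == 0) {
    return(tibble::tibble(signal = character(), times_in_topk = integer(),
                          times_used = integer(), relevance = numeric()))
  }
  tu <- table(all_used)
  tk <- table(factor(unlist(topk), levels = names(tu)))
  out <- tibble::tibble(
    signal = names(tu),
    times_in_topk = as.integer(tk),
    times_used = as.integer(tu),
    relevance = as.integer(tk) / as.integer(tu)
  )
  dplyr::arrange(out, dplyr::desc(.data$relevance))
}

#' Full evaluation report for pooled LOPO predictions
#'
#' Computes every reported performance surface from the pooled
#' cross-validation probabilities: AUROC with DeLong 95% CI, the Youden
#' operating point with sensitivity/specificity, AUPRC with its no-skill
#' baseline, the confusion matrix and accuracy at the operating threshold,
#' the LOWESS calibration curve with ICI and Emax (when at least 20
#' samples are available), and the per-signal relevance table.
#'
#' @param cv An `nv_cv` from [lopo_cv()].
#' @param k Top-k for signal relevance (default 5).
#' @return Object of class `nv_eval` with fields `auroc`, `ci_low`,
#'   `ci_high`, `sensitivity`, `specificity`, `threshold`, `auprc`,
#'   `auprc_baseline`, `accuracy`, `confusion`, `calibration` (or `NULL`),
#'   `relevance`, `curve`, `n_pos`, `n_neg`.
#' @export
evaluate_cv <- function(cv, k = 5) {
  stopifnot(inherits(cv, "nv_cv"))
  y <- cv$predictions$label; p <- cv$predictions$prob
  roc <- roc_auc(y, p)
  ci <- tryCatch(delong_ci(y, p), warning = function(w) {
    a <- roc$auroc; c(a, a)
  })
  op <- operating_point(roc$curve)
  pr <- auprc_with_baseline(y, p)
  cm <- confusion_accuracy(y, p, op$threshold)
  cal <- if (length(y) >= 20) calibration_report(y, p) else NULL
  structure(list(
    auroc = roc$auroc, ci_low = ci[1], ci_high = ci[2],
    sensitivity = op$sensitivity, specificity = op$specificity,
    threshold = op$threshold,
    auprc = pr$auprc, auprc_baseline = pr$baseline,
    accuracy = cm$accuracy, confusion = cm$matrix,
    calibration = cal, relevance = signal_relevance(cv, k),
    curve = roc$curve, n_pos = sum(y == 1), n_neg = sum(y == 0)
  ), class = "nv_eval")
}

#' @export
print.nv_eval <- function(x, ...) {
  cat(sprintf(
    "<nv_eval> AUROC %.3f (95%% CI %.3f-%.3f), AUPRC %.3f (baseline %.3f)\n",
    x$auroc, x$ci_low, x$ci_high, x$auprc, x$auprc_baseline))
  cat(sprintf("  operating point: sens %.2f, spec %.2f at %.3f; accuracy %.3f\n",
              x$sensitivity, x$specificity, x$threshold, x$accuracy))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibration: ICI %.3f, Emax %.3f\n",
                x$calibration$ici, x$calibration$emax))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-signal relevance table of an evaluation
#'
#' @param x An `nv_eval`.
#' @param ... Unused.
#' @return Tibble with one row per signal (`signal, times_in_topk,
#'   times_used, relevance`).
#' @exportS3Method generics::tidy
tidy.nv_eval <- function(x, ...) x$relevance

#' One-row summary of an evaluation
#'
#' @param x An `nv_eval`.
#' @param ... Unused.
#' @return One-row tibble with the headline metrics.
#' @exportS3Method generics::glance
glance.nv_eval <- function(x, ...) {
  tibble::tibble(
    auroc = x$auroc, ci_low = x$ci_low, ci_high = x$ci_high,
    sensitivity = x$sensitivity, specificity = x$specificity,
    threshold = x$threshold, auprc = x$auprc,
    auprc_baseline = x$auprc_baseline, accuracy = x$accuracy,
    ici = if (is.null(x$calibration)) NA_real_ else x$calibration$ici,
    emax = if (is.null(x$calibration)) NA_real_ else x$calibration$emax,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}
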