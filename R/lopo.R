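#' Model and tuning configuration for LOPO cross-validation
#'
#' Gradient-boosted-tree settings for the leave-one-patient-out scheme.
#' The default grid covers the four tuned hyperparameters (gamma, minimum
#' child weight, maximum tree depth, learning rate); inner model selection
#' uses patient-grouped 5-fold cross-validation with early stopping, and
#' ties are broken towards the simpler model (smaller depth, then smaller
#' learning rate).
#'
#' @param grid Named list of candidate values for `gamma`,
#'   `min_child_weight`, `max_depth`, `learning_rate`; all combinations
#'   are searched.
#' @param n_estimators Maximum boosting rounds (early stopping on inner
#'   folds picks the effective number).
#' @param early_stopping_rounds Early-stopping patience on inner folds.
#' @param inner_folds Number of patient-grouped inner folds (>= 2).
#' @param feature_selection `"none"` (default) or `"importance_topN"`:
#'   keep the `top_n` training columns by gain importance of a
#'   preliminary fit.
#' @param top_n Number of columns kept when selection is enabled.
#' @param seed Integer seed controlling fold assignment and the learner.
#' @return A list of class `nv_model_config`.
#' @export
model_config <- function(grid = list(gamma = c(0, 1),
                                     min_child_weight = c(1, 5),
                                     max_depth = c(2, 4, 6),
                                     learning_rate = c(0.05, 0.1, 0.3)),
                         n_estimators = 200, early_stopping_rounds = 20,
                         inner_folds = 5,
                         feature_selection = c("none", "importance_topN"),
                         top_n = 20, seed = 1L) {
  feature_selection <- match.arg(feature_selection)
  stopifnot(length(grid) > 0, all(lengths(grid) >= 1), inner_folds >= 2)
  default_grid <- list(gamma = 0, min_child_weight = 1, max_depth = 4,
                       learning_rate = 0.1)
  for (p in setdiff(names(default_grid), names(grid))) {
    grid[[p]] <- default_grid[[p]]
  }
  structure(list(grid = grid, n_estimators = n_estimators,
                 early_stopping_rounds = early_stopping_rounds,
                 inner_folds = inner_folds,
                 feature_selection = feature_selection, top_n = top_n,
                 seed = as.integer(seed)),
            class = "nv_model_config")
}

feature_columns <- function(dataset) {
  names(dataset)[grepl("__", names(dataset), fixed = TRUE)]
}

signal_of_column <- function(cols) sub("__.*$", "", cols)

xgb_fit <- function(X, y, params, nrounds, val = NULL,
                    early_stopping_rounds = NULL) {
  w <- rep(1, length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  # cost reweighting: the smaller class gets weight larger/smaller
  if (n1 > 0 && n0 > 0 && n1 != n0) {
    small <- if (n1 < n0) 1 else 0
    w[y == small] <- max(n0, n1) / min(n0, n1)
  }
  d <- xgboost::xgb.DMatrix(X, label = y, weight = w)
  p <- xgboost::xgb.params(
    objective = "binary:logistic", eval_metric = "auc", nthread = 1,
    gamma = params$gamma, min_child_weight = params$min_child_weight,
    max_depth = params$max_depth, learning_rate = params$learning_rate,
    seed = params$seed %||% 0
  )
  if (is.null(val)) {
    xgboost::xgb.train(params = p, data = d, nrounds = nrounds,
                       verbose = 0)
  } else {
    dv <- xgboost::xgb.DMatrix(val$X, label = val$y)
    xgboost::xgb.train(params = p, data = d, nrounds = nrounds,
                       evals = list(val = dv),
                       early_stopping_rounds = early_stopping_rounds,
                       verbose = 0)
  }
}

group_folds <- function(patient_ids, k) {
  pts <- unique(patient_ids)
  k <- min(k, length(pts))
  assign_ <- stats::setNames(rep(seq_len(k), length.out = length(pts)),
                             sample(pts))
  unname(assign_[patient_ids])
}

#' Tune hyperparameters by patient-grouped inner cross-validation
#'
#' Searches all combinations of the configured grid; each point is scored
#' by the mean validation AUROC over patient-grouped inner folds, trained
#' with early stopping. The grid point with the highest mean AUROC wins;
#' ties are broken towards smaller `max_depth`, then smaller
#' `learning_rate`. The returned `nrounds` is the mean early-stopped best
#' iteration of the winning point, used to re-train on the full training
#' data.
#'
#' @param X Numeric feature matrix (may contain `NA`).
#' @param y Binary labels.
#' @param patient_ids Patient id per row (grouping for the inner folds).
#' @param cfg An [model_config()].
#' @return List `params` (winning grid point), `nrounds`, `score` (mean
#'   inner AUROC).
#' @export
tune_hyperparameters <- function(X, y, patient_ids, cfg = model_config()) {
  if (length(unique(y)) < 2) {
    stop("training fold must contain both classes", call. = FALSE)
  }
  set.seed(cfg$seed)
  fold <- group_folds(patient_ids, cfg$inner_folds)
  grid <- expand.grid(cfg$grid, KEEP.OUT.ATTRS = FALSE)
  scores <- numeric(nrow(grid)); iters <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    par <- as.list(grid[g, ]); par$seed <- cfg$seed
    aucs <- c(); bi <- c()
    for (f in unique(fold)) {
      tr <- fold != f; va <- !tr
      if (length(unique(y[va])) < 2 || length(unique(y[tr])) < 2) next
      m <- xgb_fit(X[tr, , drop = FALSE], y[tr], par,
                   nrounds = cfg$n_estimators,
                   val = list(X = X[va, , drop = FALSE], y = y[va]),
                   early_stopping_rounds = cfg$early_stopping_rounds)
      pv <- stats::predict(m, xgboost::xgb.DMatrix(X[va, , drop = FALSE]))
      aucs <- c(aucs, roc_auc(y[va], pv)$auroc)
      bb <- xgboost::xgb.attributes(m)$best_iteration
      bi <- c(bi, if (is.null(bb)) cfg$n_estimators else
        as.integer(bb) + 1L)
    }
    scores[g] <- if (length(aucs)) mean(aucs) else NA_real_
    iters[g] <- if (length(bi)) mean(bi) else cfg$n_estimators
  }
  if (all(is.na(scores))) {
    stop("no usable inner folds: every fold was single-class",
         call. = FALSE)
  }
  ord <- order(-scores, grid$max_depth, grid$learning_rate)
  best <- ord[1]
  list(params = c(as.list(grid[best, ]), seed = cfg$seed),
       nrounds = max(1L, as.integer(round(iters[best]))),
       score = scores[best])
}

#' Select training columns by gain importance
#'
#' With `feature_selection = "importance_topN"`, fits a preliminary model
#' on the training data and keeps the `top_n` columns by gain importance
#' (columns never used by the model rank last); with `"none"`, returns all
#' columns. If fewer columns are available than `top_n`, all are kept with
#' a warning.
#'
#' @param X Training feature matrix with column names.
#' @param y Binary labels.
#' @param cfg An [model_config()].
#' @return Character vector of retained column names (a subset of
#'   `colnames(X)`).
#' @export
select_features <- function(X, y, cfg = model_config()) {
  if (cfg$feature_selection == "none") return(colnames(X))
  if (length(unique(y)) < 2) {
    stop("training fold must contain both classes", call. = FALSE)
  }
  if (cfg$top_n >= ncol(X)) {
    if (cfg$top_n > ncol(X)) {
      warning("top_n exceeds available columns; keeping all")
    }
    return(colnames(X))
  }
  par <- list(gamma = 0, min_child_weight = 1, max_depth = 4,
              learning_rate = 0.1, seed = cfg$seed)
  m <- xgb_fit(X, y, par, nrounds = 50)
  imp <- xgboost::xgb.importance(model = m)
  ranked <- c(imp$Feature, setdiff(colnames(X), imp$Feature))
  ranked[seq_len(cfg$top_n)]
}

#' Leave-one-patient-out nested cross-validation
#'
#' One round per patient: all of the held-out patient's samples form the
#' test set, and the model is trained on the remaining patients using only
#' the features of signals actually measured for the held-out patient, so
#' that train and test share a feature space. Within each round,
#' hyperparameter tuning ([tune_hyperparameters()]), feature selection
#' ([select_features()]) and class reweighting use training data only; the
#' tuned model is re-trained on the full training data and produces
#' predicted probabilities for the held-out samples. Rounds whose training
#' data are single-class (possible in small cohorts) are skipped with a
#' warning and logged. All rounds' probabilities are pooled for
#' evaluation.
#'
#' @param dataset Labeled tibble from [build_task_dataset()]: id columns
#'   plus `label` and `signal__feature` columns.
#' @param cfg An [model_config()].
#' @return Object of class `nv_cv`:
#'   \describe{
#'     \item{predictions}{tibble `sample_id, patient_id, label, prob,
#'       round`.}
#'     \item{rounds}{list per round: `patient_id`, `signals_used`,
#'       `features_used`, `params`, `nrounds`, `importance` tibble.}
#'     \item{skipped}{tibble `patient_id, reason`.}
#'   }
#' @export
lopo_cv <- function(dataset, cfg = model_config()) {
  fcols <- feature_columns(dataset)
  stopifnot(length(fcols) > 0, "label" %in% names(dataset))
  pts <- unique(dataset$patient_id)
  if (length(pts) < 2) {
    stop("leave-one-patient-out needs at least 2 patients", call. = FALSE)
  }
  if (length(unique(dataset$label)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  X_all <- as.matrix(dataset[, fcols])
  preds <- list(); rounds <- list(); skipped <- list()
  for (r in seq_along(pts)) {
    p <- pts[r]
    te <- dataset$patient_id == p
    y_tr <- dataset$label[!te]
    if (length(unique(y_tr)) < 2) {
      warning("round ", r, " (", p, ") skipped: single-class training set")
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        patient_id = p, reason = "single-class training set")
      next
    }
    # signals measured for the held-out patient
    te_cols <- fcols[colSums(!is.na(X_all[te, , drop = FALSE])) > 0]
    sig_used <- unique(signal_of_column(te_cols))
    use_cols <- fcols[signal_of_column(fcols) %in% sig_used]
    if (length(use_cols) == 0) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        patient_id = p, reason = "no signals measured in test window")
      next
    }
    rcfg <- cfg; rcfg$seed <- cfg$seed + r
    X_tr <- X_all[!te, use_cols, drop = FALSE]
    keep_cols <- select_features(X_tr, y_tr, rcfg)
    X_tr <- X_tr[, keep_cols, drop = FALSE]
    tuned <- tryCatch(
      tune_hyperparameters(X_tr, y_tr, dataset$patient_id[!te], rcfg),
      error = function(e) NULL)
    if (is.null(tuned)) {
      # untunable round (e.g. every inner fold single-class in a tiny
      # cohort): train with the simplest grid point instead
      warning("round ", r, " (", p, "): inner tuning not possible, ",
              "using the simplest grid point")
      gr <- expand.grid(rcfg$grid, KEEP.OUT.ATTRS = FALSE)
      gr <- gr[order(gr$max_depth, gr$learning_rate), , drop = FALSE]
      tuned <- list(params = c(as.list(gr[1, ]), seed = rcfg$seed),
                    nrounds = rcfg$n_estimators, score = NA_real_)
    }
    m <- xgb_fit(X_tr, y_tr, tuned$params, nrounds = tuned$nrounds)
    pv <- stats::predict(
      m, xgboost::xgb.DMatrix(X_all[te, keep_cols, drop = FALSE]))
    preds[[length(preds) + 1]] <- tibble::tibble(
      sample_id = dataset$sample_id[te], patient_id = p,
      label = dataset$label[te], prob = pv, round = r)
    imp <- xgboost::xgb.importance(model = m)
    rounds[[length(rounds) + 1]] <- list(
      patient_id = p, signals_used = unique(signal_of_column(keep_cols)),
      features_used = keep_cols,
      params = tuned$params, nrounds = tuned$nrounds,
      importance = tibble::tibble(feature = imp$Feature, gain = imp$Gain))
  }
  structure(list(predictions = dplyr::bind_rows(preds), rounds = rounds,
                 skipped = dplyr::bind_rows(skipped), config = cfg),
            class = "nv_cv")
}

#' @export
print.nv_cv <- function(x, ...) {
  cat("<nv_cv> ", length(x$rounds), " LOPO rounds, ",
      nrow(x$predictions), " pooled predictions",
      if (nrow(x$skipped)) paste0(" (", nrow(x$skipped),
                                  " rounds skipped)"), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
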