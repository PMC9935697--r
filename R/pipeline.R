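#' Run the full pipeline on a synthetic cohort
#'
#' Convenience wrapper chaining every stage: generate (or accept) a
#' cohort, preprocess it into pre-assessment windows, extract wavelet
#' denoised features for a variable subset, build the labeled task
#' dataset, run leave-one-patient-out nested cross-validation, and
#' evaluate the pooled predictions.
#'
#' @param cohort An `nv_cohort`, or an [cohort_config()] to generate one.
#' @param task Task name or [task_spec()] (default `"comavs_vs_mcscf"`,
#'   the split with the most balanced synthetic classes).
#' @param subset Variable subset (default `"hospital"`).
#' @param window_cfg,feature_cfg,model_cfg Stage configurations.
#' @return List of class `nv_pipeline`: `cohort`, `windows`, `features`,
#'   `dataset`, `cv`, `eval`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(cohort_config(n_patients = 6, signals = c("HR", "RR"),
#'                                   effect_size = 3, seed = 42),
#'                     model_cfg = model_config(grid = list(max_depth = 3),
#'                                              inner_folds = 3))
#' glance(res$eval)
#' }
run_pipeline <- function(cohort, task = "comavs_vs_mcscf",
                         subset = "hospital",
                         window_cfg = window_config(),
                         feature_cfg = feature_config(),
                         model_cfg = model_config()) {
  if (inherits(cohort, "nv_cohort_config")) cohort <- generate_cohort(cohort)
  stopifnot(inherits(cohort, "nv_cohort"))
  if (is.character(task)) task <- task_spec(task)
  windows <- preprocess_cohort(cohort, window_cfg)
  features <- build_feature_matrix(windows, subset, feature_cfg)
  dataset <- build_task_dataset(features, task)
  cv <- lopo_cv(dataset, model_cfg)
  ev <- evaluate_cv(cv)
  structure(list(cohort = cohort, windows = windows, features = features,
                 dataset = dataset, cv = cv, eval = ev),
            class = "nv_pipeline")
}

#' @export
print.nv_pipeline <- function(x, ...) {
  print(x$eval)
  invisible(x)
}
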