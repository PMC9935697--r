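#' Map behavioral scores to consciousness categories
#'
#' The six-point behavioral scale is grouped into four clinically relevant
#' categories: score 0 is coma; 1 is vegetative state / unresponsive
#' wakefulness syndrome (VS/UWS); 2 or 3 is minimally conscious state minus
#' (MCS-); 4 or 5 is command following (CF).
#'
#' @param score Integer vector with values in 0--5.
#' @return Factor with levels `coma`, `VS_UWS`, `MCS_minus`, `CF`.
#' @export
#' @examples
#' map_score_to_category(c(0, 1, 3, 5))
map_score_to_category <- function(score) {
  if (any(is.na(score)) || any(score != as.integer(score)) ||
      any(score < 0 | score > 5)) {
    stop("behavioral scores must be integers in 0..5", call. = FALSE)
  }
  lv <- c("coma", "VS_UWS", "MCS_minus", "CF")
  idx <- c(1L, 2L, 3L, 3L, 4L, 4L)[score + 1]
  factor(lv[idx], levels = lv)
}

#' Binary classification task definitions
#'
#' The three clinically motivated binary tasks:
#' \describe{
#'   \item{vs_vs_mcs}{VS/UWS versus MCS- (presence of minimal awareness).}
#'   \item{comavs_vs_mcscf}{\{coma, VS/UWS\} versus \{MCS-, CF\}
#'     (prognostically relevant split).}
#'   \item{noncf_vs_cf}{non-CF (coma, VS/UWS, MCS-) versus CF (ability to
#'     follow commands).}
#' }
#'
#' @param name Task name.
#' @return A list of class `nv_task` with `name`, `side_a`, `side_b`
#'   (character vectors of categories). Which side is the positive class is
#'   decided per dataset by [build_task_dataset()] (minority convention).
#' @export
task_spec <- function(name = c("vs_vs_mcs", "comavs_vs_mcscf",
                               "noncf_vs_cf")) {
  name <- match.arg(name)
  sides <- switch(name,
    vs_vs_mcs = list(a = "VS_UWS", b = "MCS_minus"),
    comavs_vs_mcscf = list(a = c("coma", "VS_UWS"),
                           b = c("MCS_minus", "CF")),
    noncf_vs_cf = list(a = c("coma", "VS_UWS", "MCS_minus"), b = "CF")
  )
  stopifnot(length(intersect(sides$a, sides$b)) == 0)
  structure(list(name = name, side_a = sides$a, side_b = sides$b),
            class = "nv_task")
}

#' Build a labeled dataset for a binary task
#'
#' Filters a feature matrix to the rows whose category belongs to the task,
#' and attaches a binary `label` column. The positive class (label 1) is by
#' convention the minority class of the two task sides in the given data,
#' so the AUPRC no-skill baseline equals minority prevalence; ties go to
#' side A. Patient ids are preserved for leave-one-patient-out grouping.
#'
#' @param features A feature matrix tibble from [build_feature_matrix()]
#'   (needs `category` and `patient_id` columns).
#' @param task An [task_spec()] object.
#' @param positive Optional override: `"minority"` (default), `"a"` or
#'   `"b"` to force a side to be positive.
#' @return The filtered tibble with an integer `label` column and
#'   attributes `task` and `positive_categories`.
#' @export
build_task_dataset <- function(features, task, positive = "minority") {
  stopifnot(inherits(task, "nv_task"))
  cat_col <- as.character(features$category)
  keep <- cat_col %in% c(task$side_a, task$side_b)
  out <- features[keep, , drop = FALSE]
  in_a <- as.character(out$category) %in% task$side_a
  n_a <- sum(in_a); n_b <- sum(!in_a)
  if (n_a == 0 || n_b == 0) {
    stop("task `", task$name, "`: one side has no samples (",
         "side A n=", n_a, ", side B n=", n_b, ")", call. = FALSE)
  }
  pos_is_a <- switch(positive,
    minority = n_a <= n_b,
    a = TRUE,
    b = FALSE,
    stop("`positive` must be 'minority', 'a' or 'b'", call. = FALSE)
  )
  out$label <- as.integer(if (pos_is_a) in_a else !in_a)
  attr(out, "task") <- task
  attr(out, "positive_categories") <- if (pos_is_a) task$side_a else task$side_b
  out
}

#' Class-imbalance weight for the smaller class
#'
#' Ratio of the larger to the smaller class size; used as the positive-class
#' training weight (cost reweighting) so that misclassifying the minority
#' class is penalized proportionally to the imbalance.
#'
#' @param labels Binary vector (0/1) of training labels.
#' @return Scalar weight >= 1; exactly 1 for balanced classes.
#' @export
#' @examples
#' positive_weight(c(rep(1, 54), rep(0, 67)))
positive_weight <- function(labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute a class weight",
         call. = FALSE)
  }
  max(n0, n1) / min(n0, n1)
}
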