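## End-to-end orchestration: radiome extraction per (subject, observer),
## cohort-level feature tables, and the full simulate -> extract ->
## reproducibility -> CV study -> select -> train -> evaluate run.

#' Extract the 87-feature radiome of one masked image
#'
#' Computes, in canonical order: 6 size + 5 shape features from the mask,
#' 14 intensity-distribution features from the raw masked intensities, the
#' 52 image-domain texture features (GLCM/GLRLM/GLSZM/NGTDM averaged over
#' directions and the discretization sweep), and 10 Gabor filter-bank
#' features.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical (or 0/1) mask, same shape.
#' @param spacing Pixel spacing in mm (scalar or `(row, col)`).
#' @param levels Discretization level sweep.
#' @param bank Gabor bank (defaults to the pipeline bank).
#' @return Named numeric vector of 87 features.
#' @export
extract_features <- function(image, mask, spacing = c(1, 1),
                             levels = .default_levels,
                             bank = build_gabor_bank()) {
  m <- .stopifnot_mask(mask)
  out <- c(size_features(m, spacing),
           shape_features(m),
           intensity_features(image[m]),
           aggregate_texture(image, m, levels),
           gabor_features(image, m, bank))
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Extract the feature table of a cohort
#'
#' One row per (subject, observer): metadata columns `subject_id`,
#' `observer`, `class_label`, `vendor` followed by the 87 feature columns.
#' Failures are reported with the subject id; with `skip_errors = TRUE` the
#' failing subject is dropped instead.
#'
#' @param cohort A `phantom_cohort` (or list of `phantom_subject`).
#' @param levels Discretization level sweep.
#' @param observers Observer masks to extract (subset of `c(1, 2)`).
#' @param skip_errors Drop failing subjects instead of stopping.
#' @return Feature table data.frame.
#' @export
extract_all <- function(cohort, levels = .default_levels,
                        observers = c(1L, 2L), skip_errors = FALSE) {
  bank <- build_gabor_bank()
  rows <- list()
  for (s in cohort) {
    for (obs in observers) {
      mask <- if (obs == 1L) s$mask_obs1 else s$mask_obs2
      feats <- tryCatch(
        extract_features(s$image, mask, s$pixel_spacing_mm, levels, bank),
        error = function(e) {
          msg <- paste0("extraction failed for ", s$subject_id,
                        " observer ", obs, ": ", conditionMessage(e))
          if (skip_errors) { warning(msg); NULL } else stop(msg)
        })
      if (is.null(feats)) next
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject_id = s$subject_id, observer = obs,
                   class_label = s$class_label, vendor = s$vendor,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(feats)))
    }
  }
  if (length(rows) == 0) stop("no subject extracted")
  tab <- do.call(rbind, rows)
  names(tab) <- c(.ft_meta_cols, feature_names())
  tab
}

#' Run the full pipeline
#'
#' Generates (or reuses) a phantom cohort, extracts both observers'
#' feature tables, computes the reproducibility report and the
#' discretization-stability study, applies the dual filter, trains the
#' linear SVM on a stratified holdout of the observer-1 rows and evaluates
#' it on the held-out subjects. All artifacts are written as CSV/JSON under
#' `out_dir` when given.
#'
#' @param spec A `cohort_spec` (its `seed` drives the cohort; the same seed
#'   also drives the CV-study subject draw and the holdout split unless a
#'   `selection_config` with its own seed is supplied).
#' @param config A `selection_config`.
#' @param levels Discretization level sweep.
#' @param out_dir Optional output directory for artifacts.
#' @param cv_n_per_group Subjects per class in the CV study (default 10).
#' @param run_cv_study Set `FALSE` to skip the (slower) CV study.
#' @return List with `cohort`, `features`, `reproducibility`, `cv`,
#'   `selected`, `model`, `evaluation`, `split`.
#' @export
run_pipeline <- function(spec = cohort_spec(), config = selection_config(seed = spec$seed),
                         levels = .default_levels, out_dir = NULL,
                         cv_n_per_group = 10, run_cv_study = TRUE) {
  cohort <- generate_cohort(spec)
  features <- extract_all(cohort, levels)
  repro <- reproducibility_report(features, config$r_threshold)
  cv <- if (run_cv_study)
    cv_study(cohort, cv_n_per_group, levels, seed = spec$seed) else NULL
  selected <- dual_filter(features, repro, config)
  if (length(selected) == 0) stop("dual filter selected no feature")
  o1 <- features[features$observer == 1, , drop = FALSE]
  split <- stratified_holdout(o1, config$train_fraction, config$seed)
  model <- train_svm(split$train, selected, config)
  evaluation <- evaluate_model(model, split$test)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    write_feature_table(features, file.path(out_dir, "features.csv"))
    data.table::fwrite(repro$per_feature,
                       file.path(out_dir, "reproducibility.csv"))
    data.table::fwrite(repro$per_family,
                       file.path(out_dir, "reproducibility_families.csv"))
    if (!is.null(cv))
      data.table::fwrite(as.data.frame(cv), file.path(out_dir, "cv_study.csv"))
    writeLines(selected, file.path(out_dir, "selected_features.txt"))
    write_model_bundle(model, file.path(out_dir, "model.json"))
    data.table::fwrite(evaluation$metrics, file.path(out_dir, "metrics.csv"))
    jsonlite::write_json(
      list(confusion = as.list(evaluation$confusion),
           auroc = evaluation$auroc,
           n_selected = length(selected),
           seed = spec$seed),
      file.path(out_dir, "evaluation.json"), digits = NA, auto_unbox = TRUE)
  }
  list(cohort = cohort, features = features, reproducibility = repro,
       cv = cv, selected = selected, model = model,
       evaluation = evaluation, split = split)
}
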