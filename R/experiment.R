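#' Run one end-to-end classification experiment
#'
#' Wires the full study pipeline on a cohort of recordings: preprocess each
#' recording into windows, split subjects (stratified, cross-individual),
#' train the transformer with the chosen objective, predict test windows,
#' aggregate to patient level by majority vote, and evaluate at both levels
#' over the same test subjects. Eyes-open and eyes-closed recordings are
#' separate experiments, never mixed in one model.
#'
#' @param recordings List of labeled [eeg_recording]s (e.g.
#'   `generate_cohort(...)$recordings`), all from the same condition.
#' @param class_set `"five"` (MDD/ADHD/SMC/OCD/Healthy), `"three"`
#'   (MDD/ADHD/SMC: minority classes dropped before splitting), or a
#'   character vector of class names to keep; `NULL` keeps all labels
#'   present.
#' @param preprocess A [preprocess_config].
#' @param model_cfg A [model_config]; `num_classes`, `input_steps` and
#'   `input_channels` must match the class set and preprocessing geometry.
#' @param loss A [loss_config].
#' @param train_cfg A [train_config].
#' @param split_seed Seed for the subject split.
#' @param out_dir Optional run directory; when given, the manifest, metric
#'   history and both evaluation reports are written there as JSON/CSV and
#'   the trained model as an RDS checkpoint.
#' @return A list with the trained `model`, the `split`, `window_report`
#'   and `patient_report` ([evaluate_predictions]), window predictions, and
#'   the patient-level votes.
#' @export
run_experiment <- function(recordings, class_set = NULL,
                           preprocess = preprocess_config(),
                           model_cfg = model_config(),
                           loss = loss_config("cce"),
                           train_cfg = train_config(),
                           split_seed = 1L, out_dir = NULL) {
  stopifnot(length(recordings) > 0L)
  keep <- if (is.null(class_set)) NULL
          else if (identical(class_set, "five")) c("MDD", "ADHD", "SMC", "OCD", "Healthy")
          else if (identical(class_set, "three")) c("MDD", "ADHD", "SMC")
          else as.character(class_set)
  labels <- vapply(recordings, function(r) r$label %||% NA_character_, "")
  if (anyNA(labels)) stop("all recordings must carry labels", call. = FALSE)
  if (!is.null(keep)) {
    dropped <- sum(!labels %in% keep)
    if (dropped > 0L)
      message("dropping ", dropped, " subject(s) outside the class set")
    recordings <- recordings[labels %in% keep]
    labels <- labels[labels %in% keep]
  }
  class_levels <- sort(unique(labels))
  if (length(class_levels) != model_cfg$num_classes)
    stop(sprintf("model is configured for %d classes but the cohort has %d",
                 model_cfg$num_classes, length(class_levels)), call. = FALSE)

  ws <- preprocess_cohort(recordings, preprocess)
  if (ws$m != model_cfg$input_steps || ws$e != model_cfg$input_channels)
    stop(sprintf("preprocessing yields %d x %d windows but the model expects %d x %d",
                 ws$m, ws$e, model_cfg$input_steps, model_cfg$input_channels),
         call. = FALSE)
  subj_labels <- stats::setNames(labels, vapply(recordings, `[[`, "", "subject_id"))
  split <- split_subjects(subj_labels, seed = split_seed)
  tr <- filter_subjects(ws, split$train)
  va <- filter_subjects(ws, split$val)
  te <- filter_subjects(ws, split$test)

  model <- init_transformer(model_cfg, seed = train_cfg$seed)
  model <- train_transformer(model, tr, va, loss = loss, config = train_cfg,
                             class_levels = class_levels)

  pw <- predict_windows(model, te)
  window_report <- evaluate_predictions(pw$truth, pw$pred, class_levels,
                                        level = "window")
  votes <- majority_vote(pw$pred, pw$subject_id, pw$probs, class_levels)
  truth_by_subj <- subj_labels[votes$subject_id]
  patient_report <- evaluate_predictions(unname(truth_by_subj), votes$pred,
                                         class_levels, level = "patient")

  result <- list(model = model, split = split,
                 window_report = window_report,
                 patient_report = patient_report,
                 window_predictions = pw, votes = votes,
                 class_levels = class_levels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    saveRDS(model, file.path(out_dir, "model.rds"))
    report_json <- function(r) list(level = r$level, accuracy = r$accuracy,
                                    precision = r$precision, recall = r$recall,
                                    f1 = r$f1, confusion = r$confusion,
                                    per_class = r$per_class)
    jsonlite::write_json(
      list(class_levels = class_levels,
           split = split[c("train", "val", "test", "seed")],
           loss = model$loss[c("kind", "gamma", "reduction")],
           class_weights = model$loss$weights,
           best_epoch = model$best_epoch,
           stopped_epoch = model$stopped_epoch,
           train_seed = model$train_seed, init_seed = model$init_seed,
           window = report_json(window_report),
           patient = report_json(patient_report)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a
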