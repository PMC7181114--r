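# Leave-one-subject-out and cross-dataset evaluation harnesses with
# per-subject accuracy reporting.

#' Split a cohort for leave-one-subject-out evaluation
#'
#' All recordings of the held-out subject form the test set; every other
#' recording forms the training pool. The later train/validation split happens
#' inside [train_model()] over the training pool only, so the held-out subject
#' contributes zero windows to training or validation.
#'
#' @param cohort list of `eeg_recording`s.
#' @param held_out subject id to exclude completely from training.
#' @return list with elements `train` and `test` (lists of recordings).
#' @export
loso_split <- function(cohort, held_out) {
  ids <- vapply(cohort, `[[`, "", "subject_id")
  if (!held_out %in% ids)
    stopf("unknown subject '%s'; cohort has: %s", held_out,
          paste(unique(ids), collapse = ", "))
  list(train = cohort[ids != held_out], test = cohort[ids == held_out])
}

#' Classification accuracy in percent
#'
#' `100 * (#matching labels / length)`.
#'
#' @param pred a `prediction_sequence` or integer vector of predicted codes.
#' @param truth integer vector of true class codes, same length and scheme.
#' @return accuracy percentage in `[0, 100]`.
#' @export
accuracy <- function(pred, truth) {
  labels <- if (inherits(pred, "prediction_sequence")) pred$labels else pred
  if (length(labels) != length(truth))
    stopf("length mismatch: %d predictions vs %d truth labels",
          length(labels), length(truth))
  if (length(labels) == 0) stopf("empty sequences")
  100 * mean(labels == truth)
}

# Assemble the per-subject rows into a report with recomputed aggregates.
evaluation_report <- function(rows, scheme, config, audit = NULL) {
  stopifnot(all(c("subject_id", "accuracy_unfiltered", "accuracy_filtered")
                %in% names(rows)))
  structure(list(
    rows = rows,
    mean_unfiltered = mean(rows$accuracy_unfiltered),
    mean_filtered = mean(rows$accuracy_filtered),
    sd_unfiltered = stats::sd(rows$accuracy_unfiltered),
    sd_filtered = stats::sd(rows$accuracy_filtered),
    scheme = scheme,
    config = config_snapshot(config),
    audit = audit), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d subjects (%s)\n", nrow(x$rows), x$scheme))
  print(x$rows, row.names = FALSE)
  cat(sprintf("Average  %.2f (unfiltered)  %.2f (filtered)\n",
              x$mean_unfiltered, x$mean_filtered))
  cat(sprintf("Std.Dev. %.2f (unfiltered)  %.2f (filtered)\n",
              x$sd_unfiltered, x$sd_filtered))
  invisible(x)
}

# Order tensors time-major within (session, trial) for sequence filtering.
.tensor_order <- function(tensors) {
  order(vapply(tensors, `[[`, "", "session_id"),
        vapply(tensors, function(t) t$trial_index, 1L),
        vapply(tensors, function(t) t$start_sample, 1L))
}

#' Run leave-one-subject-out evaluation
#'
#' For each subject in turn: exclude the subject, preprocess and tensorize
#' everything, train the classifier on the remaining subjects (with early
#' stopping on a stratified validation split of those subjects only), predict
#' the held-out subject's windows in time order, and score accuracy before and
#' after output median filtering. Backbone features are computed once for the
#' whole cohort — the backbone is fixed, so this is a cache, not a leak; the
#' audit trail in the returned report records the subject sets used in every
#' role for every fold.
#'
#' @param cohort list of `eeg_recording`s from at least two subjects, covering
#'   at least two classes.
#' @param config a [pipeline_config()].
#' @param progress print per-fold progress lines.
#' @return an `evaluation_report` with per-subject rows, mean and sd.
#' @export
run_loso <- function(cohort, config = pipeline_config(), progress = FALSE) {
  ids <- vapply(cohort, `[[`, "", "subject_id")
  subjects <- unique(ids)
  if (length(subjects) < 2)
    stopf("LOSO requires >= 2 subjects (got %d)", length(subjects))
  scheme <- cohort[[1]]$scheme

  tensors <- list(); owner <- character(0)
  for (i in seq_along(cohort)) {
    tt <- prepare_tensors(cohort[[i]], config)
    tensors <- c(tensors, tt)
    owner <- c(owner, rep(ids[i], length(tt)))
  }
  if (length(unique(tensor_labels(tensors))) < 2)
    stopf("degenerate-label error: cohort windows contain a single class")
  model <- build_model(config$backbone, config$head,
                       c(config$augment$N1, config$N, config$augment$depth))
  features <- backbone_features(model, tensors)

  rows <- NULL; audit <- list()
  for (s in subjects) {
    tr <- which(owner != s); te <- which(owner == s)
    tcfg <- config$train
    tcfg$rng_seed <- derive_seed(config$seed, 5L, s)
    fit <- tryCatch(
      train_model(model, tensors[tr], tcfg, features = features[tr, , drop = FALSE]),
      error = function(e) stopf("subject %s: %s", s, conditionMessage(e)))
    ord <- .tensor_order(tensors[te])
    te <- te[ord]
    pred <- predict(fit, tensors[te], features = features[te, , drop = FALSE])
    truth <- tensor_labels(tensors[te])
    acc_raw <- accuracy(pred, truth)
    acc_flt <- accuracy(median_filter_labels(pred, config$filter), truth)
    rows <- rbind(rows, data.frame(
      subject_id = s, accuracy_unfiltered = acc_raw, accuracy_filtered = acc_flt,
      n_windows = length(te), best_epoch = fit$best_epoch,
      epochs_run = nrow(fit$history)))
    audit[[s]] <- list(held_out = s,
                       train = fit$train_provenance$train_subjects,
                       val = fit$train_provenance$val_subjects,
                       test = unique(owner[te]))
    if (progress)
      message(sprintf("held out %s: %.1f%% raw, %.1f%% filtered (%d epochs)",
                      s, acc_raw, acc_flt, nrow(fit$history)))
  }
  evaluation_report(rows, scheme, config, audit = audit)
}

#' Run cross-dataset evaluation
#'
#' Trains once on every subject of the training cohort and evaluates each
#' subject of the test cohort. Both cohorts are reduced to the two-class
#' positive/negative scheme (neutral trials dropped). `channel_map` translates
#' the configured channel names to the test cohort's montage when the two
#' datasets name electrodes differently; every configured channel must map to
#' a channel present in the test recordings.
#'
#' @param train_cohort,test_cohort lists of `eeg_recording`s.
#' @param config a [pipeline_config()].
#' @param channel_map named character vector `configured name -> test-cohort
#'   name`; `NULL` for identical montages.
#' @param progress print per-subject progress lines.
#' @return an `evaluation_report` over the test cohort's subjects.
#' @export
run_cross_dataset <- function(train_cohort, test_cohort,
                              config = pipeline_config(), channel_map = NULL,
                              progress = FALSE) {
  train_cohort <- lapply(train_cohort, to_pos_neg)
  test_cohort <- lapply(test_cohort, to_pos_neg)

  if (is.null(channel_map)) {
    channel_map <- stats::setNames(config$channels, config$channels)
  }
  missing_map <- setdiff(config$channels, names(channel_map))
  if (length(missing_map) > 0)
    stopf("mapping error: channel map missing configured channel(s): %s",
          paste(missing_map, collapse = ", "))
  for (rec in test_cohort) {
    absent <- setdiff(unname(channel_map[config$channels]), rec$channel_names)
    if (length(absent) > 0)
      stopf("mapping error: mapped channel(s) %s absent from test subject %s",
            paste(absent, collapse = ", "), rec$subject_id)
  }

  train_tensors <- list()
  for (rec in train_cohort)
    train_tensors <- c(train_tensors, prepare_tensors(rec, config))
  model <- build_model(config$backbone, config$head,
                       c(config$augment$N1, config$N, config$augment$depth))
  tcfg <- config$train
  tcfg$rng_seed <- derive_seed(config$seed, 13L)
  fit <- train_model(model, train_tensors, tcfg)

  test_config <- config
  test_config$channels <- unname(channel_map[config$channels])
  rows <- NULL; audit <- list()
  for (rec in test_cohort) {
    tt <- prepare_tensors(rec, test_config)
    tt <- tt[.tensor_order(tt)]
    pred <- predict(fit, tt)
    truth <- tensor_labels(tt)
    acc_raw <- accuracy(pred, truth)
    acc_flt <- accuracy(median_filter_labels(pred, config$filter), truth)
    rows <- rbind(rows, data.frame(
      subject_id = rec$subject_id, accuracy_unfiltered = acc_raw,
      accuracy_filtered = acc_flt, n_windows = length(tt),
      best_epoch = fit$best_epoch, epochs_run = nrow(fit$history)))
    audit[[rec$subject_id]] <- list(
      held_out = rec$subject_id,
      train = fit$train_provenance$train_subjects,
      val = fit$train_provenance$val_subjects,
      test = rec$subject_id)
    if (progress)
      message(sprintf("test subject %s: %.1f%% raw, %.1f%% filtered",
                      rec$subject_id, acc_raw, acc_flt))
  }
  evaluation_report(rows, "POS_NEG", config, audit = audit)
}

#' Write / read an evaluation report
#'
#' `write_report()` writes the per-subject table as CSV and/or the full report
#' (rows, aggregates, scheme, config snapshot) as JSON; `read_report()`
#' restores an `evaluation_report` from the JSON form, recomputing nothing.
#'
#' @param report an `evaluation_report`.
#' @param csv,json output paths (`NULL` to skip either).
#' @param path JSON path written by `write_report()`.
#' @return `write_report()`: the report, invisibly. `read_report()`: an
#'   `evaluation_report`.
#' @export
write_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report$rows, csv, row.names = FALSE)
  if (!is.null(json)) {
    obj <- list(rows = report$rows,
                mean_unfiltered = report$mean_unfiltered,
                mean_filtered = report$mean_filtered,
                sd_unfiltered = report$sd_unfiltered,
                sd_filtered = report$sd_filtered,
                scheme = report$scheme,
                config = report$config)
    jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(report)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(rows = as.data.frame(obj$rows),
                 mean_unfiltered = obj$mean_unfiltered,
                 mean_filtered = obj$mean_filtered,
                 sd_unfiltered = obj$sd_unfiltered,
                 sd_filtered = obj$sd_filtered,
                 scheme = obj$scheme,
                 config = obj$config,
                 audit = NULL), class = "evaluation_report")
}
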