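# Categorical median filtering of predicted label sequences.
#
# Emotions are assumed stable over intervals of a few seconds, so isolated
# single-window misclassifications inside a run of one class are treated as
# false detections. Each predicted label is replaced by the median of the
# ordinal valence codes (-1 negative, 0 neutral, +1 positive) in a centered
# window of `size` consecutive predictions. Ordering classes by valence makes
# the median well defined for three classes; for two classes it reduces to a
# sliding majority vote.

#' Configure the output median filter
#'
#' @param size odd window length in predictions (default 5; with the default
#'   300-sample windows at stride 250 and 200 Hz this spans about 6.5 s, i.e.
#'   roughly six seconds of signal).
#' @param edge_mode `"SHRINK"` (recompute over the truncated window at the
#'   sequence edges; default) or `"REFLECT"` (mirror-pad the sequence).
#' @param span_trials filter across trial boundaries within a subject's
#'   sequence (default `FALSE`: each contiguous trial is filtered on its own,
#'   since the emotion label may change at trial boundaries).
#' @return a `filter_config`.
#' @export
filter_config <- function(size = 5, edge_mode = c("SHRINK", "REFLECT"),
                          span_trials = FALSE) {
  edge_mode <- match.arg(edge_mode)
  if (!is_count(size) || size %% 2 == 0)
    stopf("config error: filter size must be an odd positive integer (got %s)",
          paste(size, collapse = ","))
  structure(list(size = as.integer(size), edge_mode = edge_mode,
                 span_trials = isTRUE(span_trials)),
            class = "filter_config")
}

# Median filter over an integer ordinal vector. Full interior windows have odd
# length, so the median is the middle order statistic (always one of the
# window's own values). SHRINK edge windows can have even length; the lower
# median is taken so the output is still an observed ordinal.
median_filter_ordinal <- function(v, size, edge_mode = "SHRINK") {
  n <- length(v)
  if (n == 0) return(v)
  h <- (size - 1L) %/% 2L
  out <- integer(n)
  for (i in seq_len(n)) {
    if (edge_mode == "SHRINK") {
      w <- v[max(1L, i - h):min(n, i + h)]
    } else {  # REFLECT: mirror indices at the edges
      ii <- (i - h):(i + h)
      ii <- ifelse(ii < 1L, 2L - ii, ii)
      ii <- ifelse(ii > n, 2L * n - ii, ii)
      ii <- pmin(pmax(ii, 1L), n)
      w <- v[ii]
    }
    ws <- sort.int(w)
    out[i] <- ws[(length(ws) + 1L) %/% 2L]
  }
  out
}

#' Median-filter a predicted label sequence
#'
#' Replaces each predicted class by the median ordinal valence in its centered
#' window, independently per `(subject, session, trial)` group (or per
#' `(subject, session)` when `span_trials = TRUE`) — never across subjects.
#' Probabilities are passed through unchanged; only labels are rewritten.
#'
#' @param seq a `prediction_sequence` from [predict.eeg_emotion_model()] (or a
#'   bare integer vector of class codes, treated as one contiguous group).
#' @param config a [filter_config()].
#' @param scheme class scheme, required when `seq` is a bare vector.
#' @return a filtered object of the same type.
#' @export
median_filter_labels <- function(seq, config = filter_config(), scheme = NULL) {
  if (is.numeric(seq)) {
    if (is.null(scheme)) stopf("scheme required when filtering a bare label vector")
    if (length(seq) == 0) stopf("validation error: empty label sequence")
    ords <- label_to_ordinal(seq, scheme)
    return(ordinal_to_label(
      median_filter_ordinal(ords, config$size, config$edge_mode), scheme))
  }
  if (!inherits(seq, "prediction_sequence"))
    stopf("validation error: expected a prediction_sequence or label vector")
  if (length(seq$labels) == 0) stopf("validation error: empty prediction sequence")
  prov <- seq$provenance
  group <- if (config$span_trials)
    paste(prov$subject_id, prov$session_id) else
    paste(prov$subject_id, prov$session_id, prov$trial_index)
  ords <- label_to_ordinal(seq$labels, seq$scheme)
  out <- integer(length(ords))
  for (g in unique(group)) {
    idx <- which(group == g)
    idx <- idx[order(prov$start_sample[idx])]
    out[idx] <- median_filter_ordinal(ords[idx], config$size, config$edge_mode)
  }
  seq$labels <- ordinal_to_label(out, seq$scheme)
  seq
}
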