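# The in-memory recording model: one subject-session of multi-channel EEG
# with labeled trial segments.

#' Construct an EEG recording
#'
#' A recording holds a channels-by-samples amplitude matrix (microvolts), its
#' sampling rate, ordered 10-20-system channel names, subject/session
#' identifiers, and a table of labeled trial segments. Sample indices are
#' 0-based and trials are half-open `[start, end)`; element `data[a, b]` is
#' sample `b` of channel `a`.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector, one unique name per data row.
#' @param subject_id,session_id identifier strings.
#' @param trials data.frame with integer columns `start`, `end` (0-based,
#'   half-open, within the recording) and `label` (class codes under `scheme`).
#'   May have zero rows.
#' @param scheme class scheme of the trial labels (see [scheme_codes()]).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names,
                          subject_id = "s1", session_id = "1",
                          trials = empty_trials(), scheme = "POS_NEG") {
  rec <- structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         trials = as.data.frame(trials), scheme = scheme),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

#' @rdname eeg_recording
#' @export
empty_trials <- function() {
  data.frame(start = integer(0), end = integer(0), label = integer(0))
}

#' Validate an EEG recording's invariants
#'
#' Checks the structural invariants: matrix data with finite values, one
#' unique channel name per row, positive sampling rate, and trial segments
#' `0 <= start < end <= samples` with labels valid for the recording's scheme.
#'
#' @param rec an `eeg_recording`.
#' @return `rec`, invisibly; errors on the first violated invariant.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) stopf("not an eeg_recording")
  if (!is.matrix(rec$data) || !is.numeric(rec$data))
    stopf("format error: 'data' must be a numeric channels x samples matrix")
  if (anyNA(rec$data) || any(!is.finite(rec$data)))
    stopf("validation error: 'data' contains NA/NaN/Inf values")
  if (nrow(rec$data) != length(rec$channel_names))
    stopf("format error: %d data rows but %d channel names",
          nrow(rec$data), length(rec$channel_names))
  if (anyDuplicated(rec$channel_names))
    stopf("channel error: duplicated channel names: %s",
          paste(unique(rec$channel_names[duplicated(rec$channel_names)]),
                collapse = ", "))
  if (!is_scalar_num(rec$fs) || rec$fs <= 0)
    stopf("format error: fs must be a positive scalar (got %s)",
          paste(rec$fs, collapse = ","))
  tr <- rec$trials
  if (!all(c("start", "end", "label") %in% names(tr)))
    stopf("format error: trials must have columns start, end, label")
  if (nrow(tr) > 0) {
    if (any(tr$start < 0) || any(tr$start >= tr$end))
      stopf("validation error: trials must satisfy 0 <= start < end")
    if (any(tr$end > ncol(rec$data)))
      stopf("validation error: trial end %d beyond recording length %d",
            max(tr$end), ncol(rec$data))
    label_to_ordinal(tr$label, rec$scheme)  # errors on invalid codes
  } else {
    .scheme_info(rec$scheme)
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s session %s: %d ch x %d samples @ %g Hz (%s)\n",
              x$subject_id, x$session_id, nrow(x$data), ncol(x$data), x$fs, x$scheme))
  if (nrow(x$trials) > 0) {
    secs <- (x$trials$end - x$trials$start) / x$fs
    cat(sprintf("  %d trials, %.1f-%.1f s, labels: %s\n", nrow(x$trials),
                min(secs), max(secs),
                paste(sort(unique(x$trials$label)), collapse = ",")))
  } else cat("  no trials\n")
  invisible(x)
}

#' Number of channels / samples in a recording
#' @param rec an `eeg_recording`.
#' @return integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Drop neutral trials and recode to the two-class scheme
#'
#' Cross-dataset experiments use positive/negative labels only; recordings
#' labeled under POS_NEU_NEG are reduced by discarding neutral trials and
#' recoding the remainder to POS_NEG. POS_NEG recordings pass through.
#'
#' @param rec an `eeg_recording`.
#' @return an `eeg_recording` with scheme POS_NEG.
#' @export
to_pos_neg <- function(rec) {
  if (rec$scheme == "POS_NEG") return(rec)
  ords <- label_to_ordinal(rec$trials$label, rec$scheme)
  keep <- ords != 0L
  tr <- rec$trials[keep, , drop = FALSE]
  tr$label <- ordinal_to_label(ords[keep], "POS_NEG")
  rownames(tr) <- NULL
  rec$trials <- tr
  rec$scheme <- "POS_NEG"
  validate_recording(rec)
  rec
}
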