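# Channel selection, optional bandpass, and overlap windowing.

#' Restrict a recording to selected channels
#'
#' Returns the recording with data rows restricted to `names`, in the
#' requested order. The default order for downstream windows is the canonical
#' arrangement AF1, AF2, F3, F4, F5, F6, F7, T7, T8 ([eeg_channels_default()]).
#'
#' @param rec an `eeg_recording`.
#' @param names ordered channel names to keep.
#' @return an `eeg_recording` with `length(names)` rows.
#' @export
select_channels <- function(rec, names = eeg_channels_default()) {
  validate_recording(rec)
  idx <- match(names, rec$channel_names)
  if (anyNA(idx))
    stopf("channel error: channel(s) %s not present; available: %s",
          paste(names[is.na(idx)], collapse = ", "),
          paste(rec$channel_names, collapse = ", "))
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$channel_names <- rec$channel_names[idx]
  rec
}

#' Zero-phase Butterworth bandpass of a recording
#'
#' Order-6 Butterworth applied forward-backward (zero phase) to every channel.
#' Off by default in the pipeline: the public emotion-EEG datasets are
#' distributed already band-limited; this exists for generic/synthetic inputs.
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order filter order (default 6; higher orders are numerically
#'   unstable in transposed-direct-form at EEG band edges).
#' @return a band-limited copy of `rec`, same shape.
#' @export
bandpass_recording <- function(rec, lo = 0.5, hi = 75, order = 6) {
  validate_recording(rec)
  if (!is_scalar_num(lo) || !is_scalar_num(hi) || lo <= 0 || hi <= lo)
    stopf("range error: need 0 < lo < hi")
  if (hi >= rec$fs / 2)
    stopf("range error: hi = %g Hz is not below the Nyquist frequency %g Hz",
          hi, rec$fs / 2)
  bf <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  for (i in seq_len(nrow(rec$data)))
    rec$data[i, ] <- signal::filtfilt(bf, rec$data[i, ])
  rec
}

#' Cut a recording into overlapping fixed-length windows
#'
#' Within each labeled trial, fixed-length windows of `N` samples are taken at
#' stride `N - N/6` (consecutive windows overlap by `N/6` samples). Windows
#' never cross trial boundaries; a trial shorter than `N` yields no windows;
#' trailing samples that do not fill a window are discarded. Each window
#' inherits its trial's label. `N` must be at least 75 (the convolutional
#' backbone's minimum input width) and divisible by 6 so the overlap is an
#' integer.
#'
#' @param rec an `eeg_recording` (already channel-selected).
#' @param N window length in samples (default 300).
#' @return a `window_set`: list with `windows` (each a list with `samples`
#'   matrix S x N, `label`, `scheme`, `subject_id`, `session_id`,
#'   `trial_index`, `start_sample`), plus `N`, `overlap`, `stride`.
#' @export
make_windows <- function(rec, N = 300) {
  validate_recording(rec)
  if (!is_count(N) || N < 75)
    stopf("validation error: N = %s below the backbone minimum of 75 samples",
          paste(N, collapse = ","))
  if (N %% 6 != 0)
    stopf("validation error: N = %d must be divisible by 6 so the N/6 overlap is integral", N)
  overlap <- N %/% 6L
  stride <- N - overlap
  windows <- list()
  for (t in seq_len(nrow(rec$trials))) {
    tr <- rec$trials[t, ]
    L <- tr$end - tr$start
    if (L < N) next
    starts <- seq.int(0L, L - N, by = stride)
    for (s in starts) {
      a <- tr$start + s
      windows[[length(windows) + 1L]] <- list(
        samples = rec$data[, (a + 1):(a + N), drop = FALSE],
        label = tr$label, scheme = rec$scheme,
        subject_id = rec$subject_id, session_id = rec$session_id,
        trial_index = t - 1L, start_sample = as.integer(a))
    }
  }
  structure(list(windows = windows, N = as.integer(N),
                 overlap = as.integer(overlap), stride = as.integer(stride),
                 scheme = rec$scheme),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of N = %d samples (overlap %d, stride %d)\n",
              length(x$windows), x$N, x$overlap, x$stride))
  invisible(x)
}

#' Window duration in seconds
#'
#' `N / fs`: e.g. a 300-sample window is 1.5 s at 200 Hz and 0.6 s at 500 Hz.
#'
#' @param N window length in samples.
#' @param fs sampling rate in Hz (positive).
#' @return duration in seconds.
#' @export
window_duration <- function(N, fs) {
  if (!is_scalar_num(fs) || fs <= 0) stopf("range error: fs must be positive")
  N / fs
}

#' Labels of a window set
#' @param ws a `window_set`.
#' @return integer vector of class codes, one per window.
#' @export
window_labels <- function(ws) {
  vapply(ws$windows, function(w) as.integer(w$label), 1L)
}
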