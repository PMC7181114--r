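# Synthetic multi-subject EEG cohorts with class-dependent spectral structure.
#
# Each trial's signal is a mixture of band-limited Gaussian noise components,
# one per canonical EEG band, weighted by the per-class band signature. A
# subject-specific multiplicative gain and additive offset, plus broadband
# sensor noise, emulate the cross-subject distribution shift that makes naive
# subject-independent EEG classification hard. The generator is a pure
# function of its configuration: cohorts are bit-reproducible.

#' Canonical EEG frequency bands
#'
#' Delta 1-3, theta 4-7, alpha 8-13, beta 14-30, gamma 31-50 Hz.
#'
#' @return named list of `c(lo, hi)` band edges in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 13),
       beta = c(14, 30), gamma = c(31, 50))
}

#' Default electrode montage
#'
#' The nine frontal/temporal electrodes used throughout the package, in their
#' canonical window arrangement: AF1, AF2, F3, F4, F5, F6, F7, T7, T8.
#' Emotion-related EEG changes concentrate on frontal and temporal lobes, and
#' asymmetrical electrode pairs carry valence information, which is why the
#' montage pairs left/right frontal and temporal sites.
#'
#' @return character vector of channel names.
#' @export
eeg_channels_default <- function() {
  c("AF1", "AF2", "F3", "F4", "F5", "F6", "F7", "T7", "T8")
}

.default_signatures <- function(scheme) {
  # contrasting alpha- vs beta-dominant signatures (theta-dominant neutral):
  # strong enough that band power separates classes, the regime the end-to-end
  # benchmark is designed to probe
  sig <- switch(scheme,
    POS_NEG = list(
      "0" = c(delta = 0.08, theta = 0.12, alpha = 0.55, beta = 0.17, gamma = 0.08),
      "1" = c(delta = 0.08, theta = 0.12, alpha = 0.17, beta = 0.55, gamma = 0.08)),
    POS_NEU_NEG = list(
      "0" = c(delta = 0.08, theta = 0.12, alpha = 0.55, beta = 0.17, gamma = 0.08),
      "1" = c(delta = 0.08, theta = 0.55, alpha = 0.15, beta = 0.14, gamma = 0.08),
      "2" = c(delta = 0.08, theta = 0.12, alpha = 0.17, beta = 0.55, gamma = 0.08)))
  if (is.null(sig)) stopf("config error: no default band signature for scheme %s", scheme)
  sig
}

#' Configure a synthetic EEG cohort
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_class trials per class per subject (classes alternate
#'   in time).
#' @param trial_seconds trial duration in seconds.
#' @param fs sampling rate in Hz (default 200, a common EEG rate).
#' @param channel_names electrode names (default [eeg_channels_default()]).
#' @param class_scheme `"POS_NEG"` or `"POS_NEU_NEG"`.
#' @param band_signature named list, one entry per class code (as character),
#'   each a nonnegative weight vector over the five bands of [eeg_bands()]
#'   summing to 1. `NULL` uses contrasting alpha/beta-dominant defaults.
#' @param amplitude overall rhythmic signal scale in microvolts (default 10,
#'   a typical scalp-EEG rhythm amplitude).
#' @param subject_gain_sd sd of the per-subject multiplicative gain
#'   `g_s ~ N(1, sd)` (unitless).
#' @param subject_offset_sd sd of the per-subject additive offset
#'   `o_s ~ N(0, sd)` in microvolts.
#' @param noise_sd sd of broadband white sensor noise in microvolts.
#' @param seed integer seed; the cohort is a pure function of this config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 5, n_trials_per_class = 4,
                       trial_seconds = 10, fs = 200,
                       channel_names = eeg_channels_default(),
                       class_scheme = "POS_NEG",
                       band_signature = NULL,
                       amplitude = 10,
                       subject_gain_sd = 0.1, subject_offset_sd = 1,
                       noise_sd = 1, seed = 1L) {
  if (!is_count(n_subjects) || !is_count(n_trials_per_class))
    stopf("config error: n_subjects and n_trials_per_class must be positive integers")
  if (!is_scalar_num(trial_seconds) || trial_seconds <= 0)
    stopf("config error: trial_seconds must be positive")
  if (!is_scalar_num(fs) || fs <= 0) stopf("config error: fs must be positive")
  codes <- scheme_codes(class_scheme)
  if (is.null(band_signature)) band_signature <- .default_signatures(class_scheme)
  if (!setequal(names(band_signature), as.character(codes)))
    stopf("config error: band_signature must have one entry per class code (%s)",
          paste(codes, collapse = ", "))
  bands <- names(eeg_bands())
  for (k in names(band_signature)) {
    w <- band_signature[[k]]
    if (!setequal(names(w), bands) || any(w < 0) || abs(sum(w) - 1) > 1e-8)
      stopf("config error: band_signature[['%s']] must be nonnegative weights over %s summing to 1",
            k, paste(bands, collapse = ","))
  }
  for (nm in c("subject_gain_sd", "subject_offset_sd", "noise_sd", "amplitude")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v < 0) stopf("config error: %s must be >= 0", nm)
  }
  if (max(unlist(eeg_bands())) >= fs / 2)
    stopf("config error: fs = %g too low for the gamma band (need fs > 100)", fs)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_class = as.integer(n_trials_per_class),
    trial_seconds = trial_seconds, fs = fs,
    channel_names = as.character(channel_names),
    class_scheme = class_scheme, band_signature = band_signature,
    amplitude = amplitude,
    subject_gain_sd = subject_gain_sd, subject_offset_sd = subject_offset_sd,
    noise_sd = noise_sd, seed = as.integer(seed)), class = "sim_config")
}

# Unit-sd band-limited Gaussian noise: order-4 Butterworth bandpass applied
# forward-backward (zero phase) to white noise, edge-padded to absorb filter
# transients, then rescaled to sd 1.
band_limited_noise <- function(n, fs, lo, hi) {
  pad <- max(200L, ceiling(2 * fs / lo))
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * pad))
  x <- x[(pad + 1):(pad + n)]
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate one synthetic subject
#'
#' Trials alternate over the class codes (`n_trials_per_class` each) and are
#' laid out back to back. Each trial's per-channel signal is
#' `g_s * (amplitude * sum_b sqrt(w_b) x_b(t)) + o_s + noise`, where `x_b` is
#' unit-sd band-limited noise for band `b`, `w_b` the class's band weight,
#' `g_s`/`o_s` the subject's gain and offset, and `noise` white Gaussian
#' sensor noise. Deterministic given `(config$seed, subject_index)`.
#'
#' @param config a [sim_config()].
#' @param subject_index 1-based subject index, `<= config$n_subjects`.
#' @return an `eeg_recording` with subject id `s<index>`.
#' @export
generate_subject <- function(config, subject_index) {
  if (!inherits(config, "sim_config")) stopf("config error: not a sim_config")
  if (!is_count(subject_index) || subject_index > config$n_subjects)
    stopf("config error: subject_index must be in 1..%d", config$n_subjects)
  codes <- scheme_codes(config$class_scheme)
  n_trials <- config$n_trials_per_class * length(codes)
  trial_len <- round(config$trial_seconds * config$fs)
  n_ch <- length(config$channel_names)
  bands <- eeg_bands()

  with_seed(derive_seed(config$seed, 7L, subject_index), {
    g_s <- stats::rnorm(1, mean = 1, sd = config$subject_gain_sd)
    o_s <- stats::rnorm(1, mean = 0, sd = config$subject_offset_sd)
    labels <- rep(codes, times = config$n_trials_per_class)  # alternating
    data <- matrix(0, n_ch, n_trials * trial_len)
    for (t in seq_len(n_trials)) {
      w <- config$band_signature[[as.character(labels[t])]]
      cols <- ((t - 1) * trial_len + 1):(t * trial_len)
      for (ch in seq_len(n_ch)) {
        sig <- numeric(trial_len)
        for (b in names(bands)) {
          if (w[[b]] > 0)
            sig <- sig + sqrt(w[[b]]) *
              band_limited_noise(trial_len, config$fs, bands[[b]][1], bands[[b]][2])
        }
        sig <- g_s * (config$amplitude * sig) + o_s
        if (config$noise_sd > 0)
          sig <- sig + stats::rnorm(trial_len, 0, config$noise_sd)
        data[ch, cols] <- sig
      }
    }
    eeg_recording(
      data = data, fs = config$fs, channel_names = config$channel_names,
      subject_id = sprintf("s%d", subject_index), session_id = "1",
      trials = data.frame(start = (seq_len(n_trials) - 1L) * trial_len,
                          end = seq_len(n_trials) * trial_len,
                          label = labels),
      scheme = config$class_scheme)
  })
}

#' Generate a synthetic cohort
#'
#' @param config a [sim_config()].
#' @return list of `config$n_subjects` recordings with distinct subject ids.
#' @export
generate_cohort <- function(config) {
  lapply(seq_len(config$n_subjects), function(i) generate_subject(config, i))
}
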