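# Shared fixtures and independent oracles, built in code at test time.

# A small deterministic recording with two labeled trials.
make_test_recording <- function(n_ch = 3, n_samp = 800, fs = 200,
                                scheme = "POS_NEG", seed = 7) {
  set.seed(seed)
  eeg_recording(
    data = matrix(stats::rnorm(n_ch * n_samp), n_ch, n_samp),
    fs = fs,
    channel_names = paste0("CH", seq_len(n_ch)),
    subject_id = "t1", session_id = "1",
    trials = data.frame(start = c(0L, n_samp %/% 2L),
                        end = c(n_samp %/% 2L, n_samp),
                        label = c(0L, 1L)),
    scheme = scheme)
}

# One synthetic window carrying provenance, for tensorization tests.
make_test_window <- function(S = 9, N = 300, seed = 3) {
  set.seed(seed)
  list(samples = matrix(stats::rnorm(S * N, sd = 10), S, N),
       label = 1L, scheme = "POS_NEG",
       subject_id = "t1", session_id = "1",
       trial_index = 0L, start_sample = 0L)
}

# Small-but-trainable pipeline used by the evaluation tests: full stages,
# scaled-down head and minibatch for cohorts of a few hundred windows.
benchmark_pipeline <- function(seed = 1L) {
  pipeline_config(
    head = head_config(widths = c(128, 64), n_classes = 2),
    train = train_config(batch_size = 16),
    seed = seed)
}

benchmark_sim <- function(seed = 1L, n_subjects = 5, gain_sd = 0.1) {
  sim_config(n_subjects = n_subjects, n_trials_per_class = 4,
             trial_seconds = 10, subject_gain_sd = gain_sd, seed = seed)
}

# --- independent oracles -----------------------------------------------------

# Brute-force window starts: every multiple of the stride that fits.
oracle_window_starts <- function(L, N, stride) {
  starts <- seq.int(0L, max(0L, L), by = stride)
  starts[starts + N <= L]
}

# Smallest number of noisy copies k >= 0 with S * (k + 1) >= N1.
oracle_nnc <- function(S, N1) {
  k <- 0L
  while (S * (k + 1L) < N1) k <- k + 1L
  k
}

# Sort-based median filter oracle: lower median (inverse-ECDF quantile) of the
# truncated centered window.
oracle_median_filter <- function(v, size) {
  n <- length(v); h <- (size - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    w <- v[max(1L, i - h):min(n, i + h)]
    as.integer(stats::quantile(w, 0.5, type = 1))
  }, 1L)
}

# Sliding majority vote for two-class sequences (ties -> lower ordinal).
oracle_majority_vote <- function(v, size) {
  n <- length(v); h <- (size - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    w <- v[max(1L, i - h):min(n, i + h)]
    ups <- sum(w == max(v)); downs <- length(w) - ups
    if (ups > downs) max(v) else min(v)
  }, 1L)
}

# Average-periodogram (Welch) band power of one signal.
oracle_band_power <- function(x, fs, lo, hi, seg = 256) {
  n <- length(x)
  starts <- seq(1, n - seg + 1, by = seg %/% 2)
  pows <- sapply(starts, function(s) {
    y <- x[s:(s + seg - 1)] * 1  # rectangular segments are fine for this check
    sp <- Mod(stats::fft(y))^2 / seg
    freqs <- (seq_len(seg) - 1) * fs / seg
    sum(sp[freqs >= lo & freqs <= hi])
  })
  mean(pows)
}

# Log band-power features (channels x bands) for one window matrix.
oracle_bandpower_features <- function(samples, fs) {
  bands <- eeg_bands()
  feats <- c()
  for (ch in seq_len(nrow(samples)))
    for (b in bands)
      feats <- c(feats, log(oracle_band_power(samples[ch, ], fs, b[1], b[2],
                                              seg = min(256, ncol(samples))) + 1e-12))
  feats
}
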