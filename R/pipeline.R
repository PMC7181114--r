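# End-to-end pipeline configuration and the shared preprocessing path
# (channel selection -> optional bandpass -> windowing -> tensorization).

#' Configure the full pipeline
#'
#' Aggregates every stage's parameters. Defaults are the package's standard
#' recipe: the nine-channel frontal/temporal montage, 300-sample windows with
#' 50-sample overlap, 80 x 300 x 3 tensors with sigma = 0.01 noisy copies,
#' the surrogate CNN backbone with the 1024/1024/1024/512/z dense head, Adam
#' with early stopping, and a size-5 output median filter.
#'
#' @param channels ordered channel names fed to the window (default
#'   [eeg_channels_default()]).
#' @param N window length in samples (>= 75 and divisible by 6).
#' @param bandpass `NULL` (default: datasets arrive band-limited) or `c(lo, hi)`
#'   in Hz for [bandpass_recording()].
#' @param augment an [augment_config()].
#' @param backbone a [backbone_spec()].
#' @param head a [head_config()].
#' @param train a [train_config()].
#' @param filter a [filter_config()].
#' @param seed global seed; all stage streams (augmentation noise, weight
#'   initialization, shuffling, per-fold training) are derived from it.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(channels = eeg_channels_default(), N = 300,
                            bandpass = NULL,
                            augment = augment_config(),
                            backbone = backbone_spec(),
                            head = head_config(),
                            train = train_config(),
                            filter = filter_config(),
                            seed = 1L) {
  if (!is_count(N) || N < 75 || N %% 6 != 0)
    stopf("config error: N must be an integer >= 75 and divisible by 6")
  if (!is.null(bandpass) && (length(bandpass) != 2 || bandpass[1] <= 0 ||
                             bandpass[2] <= bandpass[1]))
    stopf("config error: bandpass must be NULL or c(lo, hi) with 0 < lo < hi")
  stopifnot(inherits(augment, "augment_config"), inherits(backbone, "backbone_spec"),
            inherits(head, "head_config"), inherits(train, "train_config"),
            inherits(filter, "filter_config"))
  structure(list(channels = as.character(channels), N = as.integer(N),
                 bandpass = bandpass, augment = augment, backbone = backbone,
                 head = head, train = train, filter = filter,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Preprocess and tensorize one recording
#'
#' The shared deterministic path from a raw recording to model inputs: channel
#' selection, optional zero-phase bandpass, overlap windowing, noisy-copy
#' tensorization and per-row normalization. The augmentation stream is derived
#' from the pipeline's global seed, so the same recording always yields
#' bit-identical tensors under the same config.
#'
#' @param rec an `eeg_recording`.
#' @param config a [pipeline_config()].
#' @return list of `input_tensor`s (time-ordered, trial-major).
#' @export
prepare_tensors <- function(rec, config) {
  rec <- select_channels(rec, config$channels)
  if (!is.null(config$bandpass))
    rec <- bandpass_recording(rec, config$bandpass[1], config$bandpass[2])
  ws <- make_windows(rec, config$N)
  aug <- config$augment
  aug$seed <- derive_seed(config$seed, 3L, aug$seed)
  tensorize_windows(ws, aug)
}

# Serializable snapshot of a pipeline config (drops closures).
config_snapshot <- function(config) {
  list(channels = config$channels, N = config$N, bandpass = config$bandpass,
       augment = config$augment[c("N1", "depth", "mu", "sigma",
                                  "sigma_scale_rows", "layout", "seed")],
       backbone = config$backbone[c("kind", "pretrained", "filters", "seed")],
       head = unclass(config$head),
       train = unclass(config$train),
       filter = unclass(config$filter),
       seed = config$seed)
}
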