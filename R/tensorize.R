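# Expansion of S x N windows into backbone-sized (N1 x N x depth) input
# tensors by Gaussian noisy-copy augmentation, and per-row mean-removal
# normalization.
#
# A window of S selected channels is too short for a convolutional backbone
# expecting at least 75 rows. Each channel row is therefore kept and followed
# by NNC = ceil(N1/S) - 1 noisy copies of itself (row + i.i.d. Gaussian noise),
# which is the smallest number of copies such that S * (NNC + 1) >= N1; the
# stacked rows are truncated to exactly N1. The construction is repeated
# independently for each of `depth` slices, so slices share the original
# channel rows bit-exactly but differ in their noise draws — as if extra
# electrodes sat right next to each real one.

#' Configure noisy-copy augmentation
#'
#' @param N1 target row count of the tensor (default 80; must be >= 75, the
#'   backbone minimum).
#' @param depth number of independent slices (default 3, the backbone's
#'   expected input depth).
#' @param mu,sigma mean and standard deviation of the Gaussian copy noise
#'   (defaults 0 and 0.01). `sigma` is in the amplitude units of the data;
#'   set `sigma_scale_rows = TRUE` to scale it by each row's standard
#'   deviation instead.
#' @param sigma_scale_rows if `TRUE`, the effective noise sd for a row is
#'   `sigma * sd(row)` (relative noise); default `FALSE` (absolute).
#' @param layout `"channel_blocks"` (each original row immediately followed by
#'   its copies; default) or `"originals_first"` (all originals, then copies
#'   cycling over channels).
#' @param seed integer seed; tensors are a pure function of (window, config).
#' @return an `augment_config` list.
#' @export
augment_config <- function(N1 = 80, depth = 3, mu = 0, sigma = 0.01,
                           sigma_scale_rows = FALSE,
                           layout = c("channel_blocks", "originals_first"),
                           seed = 1L) {
  layout <- match.arg(layout)
  if (!is_count(N1) || N1 < 75)
    stopf("config error: N1 = %s must be an integer >= 75 (backbone minimum)",
          paste(N1, collapse = ","))
  if (!is_count(depth)) stopf("config error: depth must be a positive integer")
  if (!is_scalar_num(sigma) || sigma < 0) stopf("config error: sigma must be >= 0")
  if (!is_scalar_num(mu)) stopf("config error: mu must be numeric")
  structure(list(N1 = as.integer(N1), depth = as.integer(depth),
                 mu = mu, sigma = sigma,
                 sigma_scale_rows = isTRUE(sigma_scale_rows),
                 layout = layout, seed = as.integer(seed)),
            class = "augment_config")
}

#' Number of noisy copies per channel
#'
#' `NNC = ceil(N1 / S) - 1`: the smallest number of copies k >= 0 such that
#' `S * (k + 1) >= N1`, i.e. originals plus copies fill the target row count.
#'
#' @param S number of selected channels (>= 1).
#' @param N1 target row count (>= 1).
#' @return integer number of noisy copies per channel.
#' @export
#' @examples
#' compute_nnc(9, 80)   # 8
#' compute_nnc(80, 80)  # 0
compute_nnc <- function(S, N1) {
  if (!is_count(S) || !is_count(N1))
    stopf("range error: S and N1 must be positive integers")
  as.integer(ceiling(N1 / S) - 1)
}

#' Create one noisy copy of a channel row
#'
#' Adds an i.i.d. Gaussian vector (mean `mu`, sd `sigma`) to the row, drawing
#' from the current RNG stream; successive calls therefore produce distinct
#' copies.
#'
#' @param row numeric vector (one channel's window samples).
#' @param config an [augment_config()].
#' @return numeric vector of the same length.
#' @export
make_noisy_copy <- function(row, config) {
  sigma <- config$sigma
  if (config$sigma_scale_rows) sigma <- sigma * stats::sd(row)
  if (sigma == 0 && config$mu == 0) return(row)
  row + stats::rnorm(length(row), mean = config$mu, sd = sigma)
}

# Row order of one slice before truncation, as (channel, copy) pairs;
# copy 0 is the original row.
.slice_row_plan <- function(S, nnc, layout) {
  if (layout == "channel_blocks") {
    list(channel = rep(seq_len(S), each = nnc + 1L),
         copy = rep(0:nnc, times = S))
  } else {
    list(channel = c(seq_len(S), rep(seq_len(S), times = nnc)),
         copy = c(rep(0L, S), rep(seq_len(nnc), each = S)))
  }
}

#' Positions of the original channel rows in a tensor slice
#'
#' Under the default `"channel_blocks"` layout, channel `m` (0-based) sits at
#' row `m * (NNC + 1)`; all originals survive the truncation to `N1` whenever
#' `(S - 1) * (NNC + 1) <= N1 - 1`.
#'
#' @param S number of channels.
#' @param config an [augment_config()].
#' @return 1-based row indices of the original rows, one per channel.
#' @export
original_row_positions <- function(S, config) {
  nnc <- compute_nnc(S, config$N1)
  plan <- .slice_row_plan(S, nnc, config$layout)
  pos <- which(plan$copy == 0L)
  pos <- pos[pos <= config$N1]
  pos
}

#' Assemble a window into a backbone input tensor
#'
#' Builds an `N1 x N x depth` array from an `S x N` window: each slice stacks,
#' per channel, the original row followed by its `NNC` independent noisy
#' copies, then truncates to the first `N1` rows. Slices use independent noise
#' draws but share the original rows bit-exactly. The noise stream is derived
#' from `(config$seed, window provenance, slice)`, so a tensor is reproducible
#' in isolation, independent of processing order.
#'
#' @param window one element of a [make_windows()] window set.
#' @param config an [augment_config()].
#' @return an `input_tensor`: list with `values` (N1 x N x depth), `label`,
#'   `scheme`, and provenance fields.
#' @export
assemble_tensor <- function(window, config) {
  S <- nrow(window$samples)
  N <- ncol(window$samples)
  if (S > config$N1)
    stopf("configuration error: %d channels exceed N1 = %d; cannot place all original rows",
          S, config$N1)
  if (N < 75)
    stopf("validation error: window length %d below the backbone minimum of 75", N)
  nnc <- compute_nnc(S, config$N1)
  plan <- .slice_row_plan(S, nnc, config$layout)
  vals <- array(0, dim = c(config$N1, N, config$depth))
  for (d in seq_len(config$depth)) {
    slice <- with_seed(
      derive_seed(config$seed, window$subject_id, window$session_id,
                  window$trial_index, window$start_sample, d), {
      rows <- matrix(0, config$N1, N)
      for (r in seq_len(config$N1)) {
        src <- window$samples[plan$channel[r], ]
        rows[r, ] <- if (plan$copy[r] == 0L) src else make_noisy_copy(src, config)
      }
      rows
    })
    vals[, , d] <- slice
  }
  structure(list(values = vals, label = as.integer(window$label),
                 scheme = window$scheme,
                 subject_id = window$subject_id, session_id = window$session_id,
                 trial_index = window$trial_index,
                 start_sample = window$start_sample),
            class = "input_tensor")
}

#' Normalize a tensor by per-row mean removal
#'
#' Subtracts each row's mean from that row, independently per depth slice, for
#' original rows and noisy copies alike, so every row of every slice has mean
#' zero. Idempotent.
#'
#' @param tensor an `input_tensor`.
#' @return the normalized tensor.
#' @export
normalize_tensor <- function(tensor) {
  d12 <- dim(tensor$values)[1:2]
  for (d in seq_len(dim(tensor$values)[3])) {
    sl <- matrix(tensor$values[, , d], d12[1], d12[2])
    tensor$values[, , d] <- sl - rowMeans(sl)
  }
  tensor
}

#' Tensorize a window set
#'
#' Applies [assemble_tensor()] and (by default) [normalize_tensor()] to every
#' window, preserving order.
#'
#' @param ws a `window_set`.
#' @param config an [augment_config()].
#' @param normalize apply per-row mean removal (default `TRUE`).
#' @return list of `input_tensor`s.
#' @export
tensorize_windows <- function(ws, config = augment_config(), normalize = TRUE) {
  lapply(ws$windows, function(w) {
    tens <- assemble_tensor(w, config)
    if (normalize) tens <- normalize_tensor(tens)
    tens
  })
}

#' Labels of a tensor list
#' @param tensors list of `input_tensor`s.
#' @return integer vector of class codes.
#' @export
tensor_labels <- function(tensors) {
  vapply(tensors, function(t) as.integer(t$label), 1L)
}
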