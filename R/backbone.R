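# Pluggable convolutional backbones.
#
# The classifier's contract is: a backbone maps an (N1 x N x depth) input
# tensor to a fixed-length feature vector (its global-average-pooled
# convolutional activations); a dense head is then trained on those features.
#
# SURROGATE_SMALL_CNN is a self-contained feature extractor: four 3x3
# convolution / ReLU / 2x2 average-pool blocks with fixed He-initialized
# random weights drawn once from the backbone seed. Random convolutional
# features are a standard untrained-feature baseline; after rectification and
# spatial averaging they act as banks of band-/scale-selective energy
# detectors, which is the role the large pretrained backbone plays at full
# fidelity. INCEPTION_RESNET_V2 names that full-fidelity mode: the package
# validates its (75, 75) minimum input and delegates feature extraction to a
# user-supplied `features_fn` (an external model export), since the pretrained
# weights are not shipped here.

#' Specify a convolutional backbone
#'
#' @param kind `"SURROGATE_SMALL_CNN"` (built-in random-feature CNN, default)
#'   or `"INCEPTION_RESNET_V2"` (external pretrained backbone via
#'   `features_fn`).
#' @param pretrained logical flag recorded for provenance; only meaningful
#'   with an external `features_fn`.
#' @param filters per-block filter counts of the surrogate CNN.
#' @param seed seed for the surrogate's fixed random weights.
#' @param features_fn optional `function(values_array) -> numeric vector`
#'   implementing feature extraction for an external backbone.
#' @return a `backbone_spec`.
#' @export
backbone_spec <- function(kind = c("SURROGATE_SMALL_CNN", "INCEPTION_RESNET_V2"),
                          pretrained = FALSE, filters = c(8, 16, 32, 32),
                          seed = 2020L, features_fn = NULL) {
  kind <- match.arg(kind)
  if (any(filters < 1) || length(filters) < 1)
    stopf("config error: filters must be positive counts")
  structure(list(kind = kind, pretrained = isTRUE(pretrained),
                 filters = as.integer(filters), seed = as.integer(seed),
                 features_fn = features_fn,
                 min_input = c(75L, 75L)),
            class = "backbone_spec")
}

# Fixed He-initialized 3x3 conv weights for each surrogate block, as
# (9 * C_in) x C_out matrices ready for the im2col product.
.init_backbone_weights <- function(spec, depth) {
  cins <- c(depth, spec$filters[-length(spec$filters)])
  with_seed(spec$seed, {
    lapply(seq_along(spec$filters), function(l) {
      fan_in <- 9L * cins[l]
      matrix(stats::rnorm(fan_in * spec$filters[l], sd = sqrt(2 / fan_in)),
             fan_in, spec$filters[l])
    })
  })
}

# im2col gather indices for a valid 3x3 convolution over an (H, W, C) array
# stored column-major. Rows are ordered output-row-fastest so the product
# reshapes directly back into an (H-2, W-2, C_out) array.
.conv_idx <- function(H, W, C) {
  oi <- rep(seq_len(H - 2L), times = W - 2L)
  oj <- rep(seq_len(W - 2L), each = H - 2L)
  idx <- matrix(0L, length(oi), 9L * C)
  col <- 1L
  for (c0 in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    idx[, col] <- (oi + di) + (oj + dj - 1L) * H + (c0 - 1L) * H * W
    col <- col + 1L
  }
  idx
}

# 2x2 average pooling with stride 2 (floor truncation).
.pool2 <- function(x) {
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  if (H2 < 1L || W2 < 1L) return(x)
  ii <- seq_len(2L * H2); jj <- seq_len(2L * W2)
  x <- x[ii, jj, , drop = FALSE]
  (x[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , drop = FALSE] +
   x[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , drop = FALSE] +
   x[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , drop = FALSE] +
   x[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , drop = FALSE]) / 4
}

# Forward pass of the surrogate CNN for one (N1, N, depth) array; returns the
# global-average-pooled feature vector (length = last filter count).
.surrogate_forward <- function(values, weights, idx_cache) {
  x <- values
  for (l in seq_along(weights)) {
    d <- dim(x)
    key <- paste(d, collapse = "x")
    if (is.null(idx_cache[[key]])) idx_cache[[key]] <- .conv_idx(d[1], d[2], d[3])
    idx <- idx_cache[[key]]
    P <- matrix(as.vector(x)[idx], nrow(idx))
    Y <- pmax(P %*% weights[[l]], 0)
    x <- array(Y, c(d[1] - 2L, d[2] - 2L, ncol(Y)))
    x <- .pool2(x)
  }
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

#' Extract backbone features from input tensors
#'
#' Maps each tensor to its backbone feature vector (the global-average-pooled
#' convolutional activations). The backbone's weights are fixed (seeded at
#' model build), so features are deterministic and can be computed once and
#' reused across training runs and cross-validation folds without leakage.
#'
#' @param model an `eeg_emotion_model` from [build_model()].
#' @param tensors list of `input_tensor`s (homogeneous shape equal to the
#'   model's input shape).
#' @return numeric matrix, one row of features per tensor.
#' @export
backbone_features <- function(model, tensors) {
  if (length(tensors) == 0) stopf("validation error: no tensors given")
  for (t in tensors) {
    if (!all(dim(t$values) == model$input_shape))
      stopf("validation error: tensor shape (%s) does not match model input (%s)",
            paste(dim(t$values), collapse = ","),
            paste(model$input_shape, collapse = ","))
  }
  spec <- model$backbone
  if (spec$kind == "INCEPTION_RESNET_V2") {
    if (!is.function(spec$features_fn))
      stopf(paste("INCEPTION_RESNET_V2 feature extraction requires a 'features_fn'",
                  "supplying the external pretrained backbone; none was provided"))
    feats <- lapply(tensors, function(t) as.numeric(spec$features_fn(t$values)))
  } else {
    idx_cache <- new.env(parent = emptyenv())
    feats <- lapply(tensors, function(t)
      .surrogate_forward(t$values, model$conv_weights, idx_cache))
  }
  lens <- unique(vapply(feats, length, 1L))
  if (length(lens) != 1L)
    stopf("validation error: backbone returned ragged feature lengths")
  do.call(rbind, feats)
}
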