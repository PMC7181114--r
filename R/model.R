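# The classifier: pluggable convolutional backbone -> global average pooling
# -> dense head (ReLU hidden layers, softmax output), trained with Adam on
# categorical cross-entropy with L2 weight decay, batch shuffling, and
# patience-based early stopping on validation accuracy.

#' Configure the dense head
#'
#' Hidden widths default to 1024, 1024, 1024, 512 with ReLU activations,
#' followed by a softmax output layer of width `n_classes` (z). An empty
#' `widths` vector yields the ablated head (global average pooling straight
#' into the softmax layer).
#'
#' @param widths hidden dense-layer widths, in order.
#' @param n_classes number of output classes z (2 or 3).
#' @return a `head_config`.
#' @export
head_config <- function(widths = c(1024, 1024, 1024, 512), n_classes = 2) {
  if (length(widths) > 0 && (any(widths < 1) || any(widths != round(widths))))
    stopf("config error: head widths must be positive integers")
  if (!is_count(n_classes) || n_classes < 2)
    stopf("config error: n_classes must be an integer >= 2")
  structure(list(widths = as.integer(widths), n_classes = as.integer(n_classes)),
            class = "head_config")
}

#' Configure training
#'
#' Defaults follow the package's standard recipe: Adam (learning rate 1e-3),
#' categorical cross-entropy with L2 penalty 1e-4 on dense weights, batch size
#' 64, shuffling every epoch, at most 100 epochs, and early stopping when the
#' best validation accuracy has not improved (strictly, at 1e-6 tolerance) for
#' 6 consecutive epochs; the weights from the best-validation epoch are kept.
#'
#' @param learning_rate Adam step size.
#' @param l2_coeff L2 penalty coefficient on dense weights (not biases).
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without validation improvement before stopping
#'   (must be `< max_epochs`).
#' @param val_fraction fraction of training windows held out for validation,
#'   stratified by class (in `(0, 1)`).
#' @param shuffle reshuffle training windows each epoch.
#' @param rng_seed seed for weight initialization, splitting and shuffling.
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, l2_coeff = 1e-4,
                         batch_size = 64, max_epochs = 100, patience = 6,
                         val_fraction = 0.2, shuffle = TRUE, rng_seed = 1L) {
  if (!is_count(batch_size)) stopf("config error: batch_size must be >= 1")
  if (!is_count(max_epochs) || !is_count(patience) || patience >= max_epochs)
    stopf("config error: need integer 0 < patience < max_epochs")
  if (!is_scalar_num(val_fraction) || val_fraction <= 0 || val_fraction >= 1)
    stopf("config error: val_fraction must be in (0, 1)")
  if (!is_scalar_num(l2_coeff) || l2_coeff < 0)
    stopf("config error: l2_coeff must be >= 0")
  structure(list(learning_rate = learning_rate, l2_coeff = l2_coeff,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, shuffle = isTRUE(shuffle),
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Build an untrained classifier
#'
#' Assembles backbone, pooling and head into a model object and validates the
#' input shape against the backbone's (75, 75) spatial minimum. The head is
#' given seeded initial weights so the untrained model can already produce
#' (uninformative) probabilities; [train_model()] re-initializes them from its
#' own seed.
#'
#' @param backbone a [backbone_spec()].
#' @param head a [head_config()].
#' @param input_shape integer triple `(N1, N, depth)`.
#' @return an `eeg_emotion_model`.
#' @export
build_model <- function(backbone = backbone_spec(), head = head_config(),
                        input_shape = c(80, 300, 3)) {
  if (length(input_shape) != 3 || any(input_shape < 1))
    stopf("validation error: input_shape must be (N1, N, depth)")
  if (input_shape[1] < backbone$min_input[1] || input_shape[2] < backbone$min_input[2])
    stopf("validation error: input shape (%s) below the backbone minimum of (%d, %d)",
          paste(input_shape, collapse = ", "),
          backbone$min_input[1], backbone$min_input[2])
  model <- structure(
    list(backbone = backbone, head = head,
         input_shape = as.integer(input_shape),
         conv_weights = NULL, feature_dim = NULL,
         weights = NULL, classes = seq_len(head$n_classes) - 1L,
         scheme = NULL, history = NULL, best_epoch = NA_integer_,
         trained = FALSE),
    class = "eeg_emotion_model")
  if (backbone$kind == "SURROGATE_SMALL_CNN") {
    model$conv_weights <- .init_backbone_weights(backbone, input_shape[3])
    # feature dim is known (last filter bank), so give the head seeded initial
    # weights: the untrained model can already emit (uninformative) probabilities
    model$feature_dim <- backbone$filters[length(backbone$filters)]
    model$weights <- with_seed(derive_seed(backbone$seed, 17L),
                               .init_head(model$feature_dim, head))
  }
  model
}

#' @export
print.eeg_emotion_model <- function(x, ...) {
  cat(sprintf("<eeg_emotion_model> %s backbone, input (%s), head [%s] -> z = %d%s\n",
              x$backbone$kind, paste(x$input_shape, collapse = ", "),
              paste(x$head$widths, collapse = ", "), x$head$n_classes,
              if (x$trained) sprintf(" [trained, best epoch %d]", x$best_epoch)
              else " [untrained]"))
  invisible(x)
}

# He-initialized dense stack: weights W[[l]] (in x out) and biases b[[l]].
.init_head <- function(feature_dim, head) {
  dims <- c(feature_dim, head$widths, head$n_classes)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b)
}

.softmax <- function(Z) {
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

# Forward pass; returns pre-activations and activations for backprop.
.head_forward <- function(X, wts) {
  L <- length(wts$W)
  A <- list(X)
  Z <- list()
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% wts$W[[l]], 2, wts$b[[l]], "+")
    A[[l + 1]] <- if (l < L) pmax(Z[[l]], 0) else .softmax(Z[[l]])
  }
  list(A = A, Z = Z, probs = A[[L + 1]])
}

.ce_loss <- function(probs, y_idx, wts, l2) {
  p <- pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)
  -mean(log(p)) + l2 * sum(vapply(wts$W, function(w) sum(w * w), 1.0))
}

#' Number of trainable head parameters
#'
#' Weights plus biases of the dense stack: `sum over layers of (in + 1) * out`.
#'
#' @param model a built `eeg_emotion_model` (after [train_model()], or pass
#'   `feature_dim` explicitly for an untrained one).
#' @param feature_dim backbone feature dimension feeding the first dense layer.
#' @return integer parameter count.
#' @export
head_param_count <- function(model, feature_dim = model$feature_dim) {
  if (is.null(feature_dim)) stopf("feature_dim unknown; train the model or pass it")
  dims <- c(feature_dim, model$head$widths, model$head$n_classes)
  sum((dims[-length(dims)] + 1) * dims[-1])
}

#' Train the classifier
#'
#' Extracts backbone features, splits the windows into training and validation
#' sets (stratified random split by class over the windows given — callers
#' doing subject-independent evaluation must pass only training subjects'
#' windows, so held-out subjects appear in neither split), and fits the dense
#' head by minibatch Adam on categorical cross-entropy with L2 weight decay.
#' Training stops at `max_epochs` or as soon as the best validation accuracy
#' has not improved for `patience` consecutive epochs; the returned model
#' carries the weights of the best-validation epoch and the full per-epoch
#' history.
#'
#' @param model an `eeg_emotion_model` from [build_model()].
#' @param tensors list of `input_tensor`s (homogeneous shape), with labels
#'   covering at least two classes.
#' @param config a [train_config()].
#' @param features optional precomputed [backbone_features()] matrix for
#'   `tensors` (the backbone is fixed, so features may be cached).
#' @return the trained `eeg_emotion_model`.
#' @export
train_model <- function(model, tensors, config = train_config(), features = NULL) {
  labels <- tensor_labels(tensors)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stopf("degenerate-label error: training labels contain a single class (%d)",
          classes)
  if (length(classes) != model$head$n_classes)
    stopf("validation error: head configured for z = %d classes but labels contain %d",
          model$head$n_classes, length(classes))
  if (is.null(features)) features <- backbone_features(model, tensors)
  y_idx <- match(labels, classes)
  n <- nrow(features)

  with_seed(derive_seed(config$rng_seed, 11L), {
    # stratified train/validation split
    val_idx <- integer(0)
    for (k in seq_along(classes)) {
      ck <- which(y_idx == k)
      n_val <- min(length(ck) - 1L, max(1L, round(config$val_fraction * length(ck))))
      if (n_val > 0) val_idx <- c(val_idx, sample(ck, n_val))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- features[tr_idx, , drop = FALSE]; ytr <- y_idx[tr_idx]
    Xva <- features[val_idx, , drop = FALSE]; yva <- y_idx[val_idx]

    wts <- .init_head(ncol(features), model$head)
    mom <- lapply(wts$W, function(w) w * 0); momb <- lapply(wts$b, function(b) b * 0)
    vel <- lapply(wts$W, function(w) w * 0); velb <- lapply(wts$b, function(b) b * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
    L <- length(wts$W)
    lr <- config$learning_rate; l2 <- config$l2_coeff

    best_acc <- -Inf; best_wts <- wts; best_epoch <- 0L; wait <- 0L
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       train_acc = numeric(0), val_loss = numeric(0),
                       val_acc = numeric(0))

    for (epoch in seq_len(config$max_epochs)) {
      ord <- if (config$shuffle) sample(length(ytr)) else seq_along(ytr)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (bidx in batches) {
        X <- Xtr[bidx, , drop = FALSE]; yb <- ytr[bidx]
        fw <- .head_forward(X, wts)
        # backprop
        G <- fw$probs
        G[cbind(seq_along(yb), yb)] <- G[cbind(seq_along(yb), yb)] - 1
        G <- G / length(yb)
        step <- step + 1L
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        for (l in L:1) {
          gW <- crossprod(fw$A[[l]], G) + 2 * l2 * wts$W[[l]]
          gb <- colSums(G)
          if (l > 1) {
            G <- (G %*% t(wts$W[[l]])) * (fw$Z[[l - 1]] > 0)
          }
          mom[[l]] <- beta1 * mom[[l]] + (1 - beta1) * gW
          vel[[l]] <- beta2 * vel[[l]] + (1 - beta2) * gW * gW
          momb[[l]] <- beta1 * momb[[l]] + (1 - beta1) * gb
          velb[[l]] <- beta2 * velb[[l]] + (1 - beta2) * gb * gb
          wts$W[[l]] <- wts$W[[l]] - lr * (mom[[l]] / corr1) / (sqrt(vel[[l]] / corr2) + eps)
          wts$b[[l]] <- wts$b[[l]] - lr * (momb[[l]] / corr1) / (sqrt(velb[[l]] / corr2) + eps)
        }
      }
      ftr <- .head_forward(Xtr, wts)
      tr_loss <- .ce_loss(ftr$probs, ytr, wts, l2)
      tr_acc <- mean(max.col(ftr$probs, ties.method = "first") == ytr)
      if (length(yva) > 0) {
        fva <- .head_forward(Xva, wts)
        va_loss <- .ce_loss(fva$probs, yva, wts, l2)
        va_acc <- mean(max.col(fva$probs, ties.method = "first") == yva)
      } else {  # degenerate tiny input: fall back to training accuracy
        va_loss <- tr_loss; va_acc <- tr_acc
      }
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                     train_acc = tr_acc, val_loss = va_loss,
                                     val_acc = va_acc))
      if (va_acc > best_acc + 1e-6) {
        best_acc <- va_acc; best_wts <- wts; best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }

    model$weights <- best_wts
    model$feature_dim <- ncol(features)
    model$classes <- classes
    model$scheme <- tensors[[1]]$scheme
    model$history <- hist
    model$best_epoch <- best_epoch
    model$trained <- TRUE
    model$train_provenance <- list(
      train_subjects = unique(vapply(tensors[tr_idx], `[[`, "", "subject_id")),
      val_subjects = if (length(val_idx))
        unique(vapply(tensors[val_idx], `[[`, "", "subject_id")) else character(0))
    model
  })
}

#' Predict class labels for input tensors
#'
#' Runs the backbone + head forward pass on each tensor, in order, and returns
#' per-window class probabilities and argmax labels (ties broken toward the
#' lowest class code).
#'
#' @param object a trained `eeg_emotion_model`.
#' @param tensors ordered list of `input_tensor`s matching the training shape.
#' @param features optional precomputed feature matrix.
#' @param ... unused.
#' @return a `prediction_sequence`: list with `labels` (class codes),
#'   `probabilities` (windows x classes matrix, columns in class-code order),
#'   `scheme`, and `provenance` data.frame.
#' @export
predict.eeg_emotion_model <- function(object, tensors, features = NULL, ...) {
  if (is.null(object$weights))
    stopf("model has no head weights; call train_model() first")
  if (is.null(features)) features <- backbone_features(object, tensors)
  if (ncol(features) != nrow(object$weights$W[[1]]))
    stopf("validation error: feature dimension %d does not match trained model (%d)",
          ncol(features), nrow(object$weights$W[[1]]))
  probs <- .head_forward(features, object$weights)$probs
  colnames(probs) <- as.character(object$classes)
  labels <- object$classes[max.col(probs, ties.method = "first")]
  structure(list(
    labels = as.integer(labels),
    probabilities = probs,
    scheme = if (!is.null(object$scheme)) object$scheme else tensors[[1]]$scheme,
    provenance = data.frame(
      subject_id = vapply(tensors, `[[`, "", "subject_id"),
      session_id = vapply(tensors, `[[`, "", "session_id"),
      trial_index = vapply(tensors, function(t) as.integer(t$trial_index), 1L),
      start_sample = vapply(tensors, function(t) as.integer(t$start_sample), 1L))),
    class = "prediction_sequence")
}

#' @export
print.prediction_sequence <- function(x, ...) {
  cat(sprintf("<prediction_sequence> %d windows, scheme %s\n",
              length(x$labels), x$scheme))
  invisible(x)
}
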