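# Classifier construction, training dynamics, early stopping, prediction.

# Toy linearly separable tensors: each class is a fixed constant pattern, and
# the patterns differ strongly in amplitude so the backbone features of the
# two classes are far apart (learnable within a few epochs).
make_toy_tensors <- function(n_per_class = 10, shape = c(75, 78, 1), seed = 5) {
  set.seed(seed)
  pat <- list(array(rnorm(prod(shape), sd = 0.5), shape),
              array(rnorm(prod(shape), sd = 2), shape))
  tensors <- list()
  for (i in seq_len(2 * n_per_class)) {
    lab <- (i - 1L) %% 2L
    tensors[[i]] <- structure(
      list(values = pat[[lab + 1L]] + array(rnorm(prod(shape), sd = 0.01), shape),
           label = lab, scheme = "POS_NEG",
           subject_id = sprintf("s%d", (i - 1L) %/% 8L + 1L), session_id = "1",
           trial_index = i - 1L, start_sample = 0L),
      class = "input_tensor")
  }
  tensors
}

# Larger step size and small batches: toy sets have only a handful of
# minibatches per epoch, so patience-limited runs see few optimizer steps.
toy_train_config <- function(seed = 1L, max_epochs = 60) {
  train_config(learning_rate = 0.05, batch_size = 4, max_epochs = max_epochs,
               rng_seed = seed)
}

test_that("model construction validates the backbone's input minimum", {
  expect_error(build_model(input_shape = c(60, 300, 3)), "minimum of \\(75, 75\\)")
  expect_error(build_model(input_shape = c(80, 74, 3)), "minimum")
  m <- build_model(input_shape = c(75, 75, 3))   # minimum accepted
  expect_s3_class(m, "eeg_emotion_model")
  m2 <- build_model(backbone_spec("INCEPTION_RESNET_V2"),
                    input_shape = c(80, 300, 3))
  expect_s3_class(m2, "eeg_emotion_model")
  expect_error(build_model(backbone_spec("INCEPTION_RESNET_V2"),
                           input_shape = c(74, 300, 3)), "minimum")
})

test_that("an untrained head already yields normalized probabilities", {
  m <- build_model(backbone_spec(filters = c(4, 8)),
                   head = head_config(widths = c(16), n_classes = 3),
                   input_shape = c(75, 78, 1))
  tensors <- make_toy_tensors(2, shape = c(75, 78, 1))
  pred <- predict(m, tensors)
  expect_identical(ncol(pred$probabilities), 3L)
  expect_true(all(abs(rowSums(pred$probabilities) - 1) < 1e-6))
  expect_true(all(pred$probabilities >= 0))
})

test_that("head parameter count matches the closed form", {
  m <- build_model(head = head_config(widths = c(1024, 1024, 1024, 512),
                                      n_classes = 3))
  f <- m$feature_dim
  dims <- c(f, 1024, 1024, 1024, 512, 3)
  expected <- sum((dims[-length(dims)] + 1) * dims[-1])
  expect_equal(head_param_count(m), expected)
  # and the actual weight arrays carry exactly that many numbers
  n_actual <- sum(vapply(m$weights$W, length, 1)) +
    sum(vapply(m$weights$b, length, 1))
  expect_equal(n_actual, expected)
})

test_that("training separates separable data and predicts it back", {
  tensors <- make_toy_tensors(10)
  m <- build_model(backbone_spec(filters = c(4, 8)),
                   head = head_config(widths = c(16), n_classes = 2),
                   input_shape = c(75, 78, 1))
  fit <- train_model(m, tensors, toy_train_config())
  expect_true(fit$trained)
  expect_identical(utils::tail(fit$history$train_acc, 1), 1)
  pred <- predict(fit, tensors)
  expect_identical(accuracy(pred, tensor_labels(tensors)), 100)
  # order is preserved
  expect_identical(pred$provenance$trial_index,
                   vapply(tensors, function(t) t$trial_index, 1L))
})

test_that("early stopping keeps the best-validation epoch within patience", {
  tensors <- make_toy_tensors(10)
  m <- build_model(backbone_spec(filters = c(4, 8)),
                   head = head_config(widths = c(16), n_classes = 2),
                   input_shape = c(75, 78, 1))
  cfg <- toy_train_config(max_epochs = 50)
  fit <- train_model(m, tensors, cfg)
  h <- fit$history
  expect_lte(nrow(h), cfg$max_epochs)
  expect_lte(nrow(h), fit$best_epoch + cfg$patience)
  # the recorded best epoch attains the maximal validation accuracy
  expect_equal(h$val_acc[fit$best_epoch], max(h$val_acc))
  # no later epoch improves on it beyond tolerance
  if (fit$best_epoch < nrow(h))
    expect_true(all(h$val_acc[(fit$best_epoch + 1):nrow(h)] <=
                      h$val_acc[fit$best_epoch] + 1e-6))
})

test_that("degenerate labels and shape mismatches are rejected", {
  tensors <- make_toy_tensors(6)
  one_class <- Filter(function(t) t$label == 0L, tensors)
  m <- build_model(backbone_spec(filters = c(4, 8)),
                   head = head_config(widths = c(16), n_classes = 2),
                   input_shape = c(75, 78, 1))
  expect_error(train_model(m, one_class, toy_train_config()),
               "degenerate-label error")
  bad <- tensors
  bad[[1]]$values <- array(0, c(75, 80, 1))
  expect_error(backbone_features(m, bad), "validation error")
})

test_that("probability ties resolve to the lowest class code", {
  tensors <- make_toy_tensors(4)
  m <- build_model(backbone_spec(filters = c(4, 8)),
                   head = head_config(widths = c(16), n_classes = 2),
                   input_shape = c(75, 78, 1))
  fit <- train_model(m, tensors, toy_train_config())
  # zero out the output layer: logits all equal, probabilities exactly tied
  L <- length(fit$weights$W)
  fit$weights$W[[L]][] <- 0
  fit$weights$b[[L]][] <- 0
  pred <- predict(fit, tensors)
  expect_true(all(abs(pred$probabilities - 0.5) < 1e-12))
  expect_true(all(pred$labels == min(fit$classes)))
})

test_that("training is deterministic given the seed", {
  tensors <- make_toy_tensors(8)
  m <- build_model(backbone_spec(filters = c(4, 8)),
                   head = head_config(widths = c(16), n_classes = 2),
                   input_shape = c(75, 78, 1))
  f1 <- train_model(m, tensors, toy_train_config(seed = 42))
  f2 <- train_model(m, tensors, toy_train_config(seed = 42))
  expect_equal(f1$history, f2$history, tolerance = 1e-6)
  f3 <- train_model(m, tensors, toy_train_config(seed = 43))
  expect_false(isTRUE(all.equal(f1$history$train_loss, f3$history$train_loss)))
})

test_that("the ablated head (softmax only) is expressible and trainable", {
  tensors <- make_toy_tensors(8)
  m <- build_model(backbone_spec(filters = c(4, 8)),
                   head = head_config(widths = integer(0), n_classes = 2),
                   input_shape = c(75, 78, 1))
  expect_identical(length(m$weights$W), 1L)
  fit <- train_model(m, tensors, toy_train_config())
  expect_s3_class(predict(fit, tensors), "prediction_sequence")
})

test_that("external backbones plug in through features_fn", {
  tensors <- make_toy_tensors(3)
  no_fn <- build_model(backbone_spec("INCEPTION_RESNET_V2"),
                       head = head_config(widths = c(8), n_classes = 2),
                       input_shape = c(75, 78, 1))
  expect_error(backbone_features(no_fn, tensors), "features_fn")

  spec <- backbone_spec("INCEPTION_RESNET_V2",
                        features_fn = function(v) c(mean(v), stats::sd(v),
                                                    mean(abs(v))))
  m <- build_model(spec, head = head_config(widths = c(8), n_classes = 2),
                   input_shape = c(75, 78, 1))
  feats <- backbone_features(m, tensors)
  expect_identical(dim(feats), c(6L, 3L))
  fit <- train_model(m, tensors, toy_train_config())
  expect_length(predict(fit, tensors)$labels, 6L)
})
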