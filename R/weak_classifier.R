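#' Per-feature-map CNN weak classifiers
#'
#' Each of the six feature maps trains its own small convolutional network.
#' Maps 1-2 use architecture A (five conv blocks, 64/64/64/128/256 filters);
#' maps 3-6 use architecture B (six conv blocks, 64/64/64/128/128/256).
#' Every conv block is a 2x2 convolution (stride 1, same padding) followed
#' by ReLU and 2x2 max pooling; the head is a ReLU dense stage with dropout
#' 0.5 before the softmax. Training is mini-batch SGD with momentum on
#' categorical cross-entropy.
#'
#' @name weak_classifier
NULL

#' Architecture specification for a weak classifier
#'
#' @param arch `"A"` (5 conv blocks, filters 64,64,64,128,256; for maps
#'   1-2) or `"B"` (6 conv blocks, filters 64,64,64,128,128,256; for maps
#'   3-6).
#' @param input_shape `c(height, width)` of the input map.
#' @param n_classes number of identity classes.
#' @param hidden width of the dense ReLU stage.
#' @param dropout dropout rate before the softmax.
#' @param late_kernel5 if `TRUE`, the last conv layer of architecture A and
#'   the last two of architecture B use 5x5 kernels (the prose variant);
#'   the default keeps every kernel at 2x2 (the parameter-table variant).
#' @return object of class `cnn_arch_spec` with a `layers` data frame
#'   (type, n_filters, kernel, stride, padding, dropout).
#' @export
cnn_arch_spec <- function(arch = c("A", "B"), input_shape = c(64L, 128L),
                          n_classes, hidden = 128L, dropout = 0.5,
                          late_kernel5 = FALSE) {
  arch <- match.arg(arch)
  filters <- if (arch == "A") c(64L, 64L, 64L, 128L, 256L)
             else c(64L, 64L, 64L, 128L, 128L, 256L)
  ksize <- rep(2L, length(filters))
  if (late_kernel5) {
    if (arch == "A") ksize[5] <- 5L else ksize[5:6] <- 5L
  }
  L <- length(filters)
  min_side <- 2L^L
  if (input_shape[1] < min_side || input_shape[2] < min_side)
    stopf(paste0("input %dx%d too small for architecture %s: ",
                 "%d max-poolings require at least %dx%d"),
          input_shape[1], input_shape[2], arch, L, min_side, min_side)
  rows <- list()
  for (l in seq_len(L)) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "conv", n_filters = filters[l],
      kernel = sprintf("%dx%d", ksize[l], ksize[l]),
      stride = "1x1", padding = "same", dropout = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "maxpool", n_filters = 1L, kernel = "2x2", stride = "2x2",
      padding = "0x0", dropout = NA_real_)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    type = "relu-dropout", n_filters = as.integer(hidden),
    kernel = NA_character_, stride = NA_character_,
    padding = NA_character_, dropout = dropout)
  rows[[length(rows) + 1L]] <- data.frame(
    type = "softmax", n_filters = as.integer(n_classes),
    kernel = NA_character_, stride = NA_character_,
    padding = NA_character_, dropout = NA_real_)
  structure(list(arch = arch, filters = filters, ksize = ksize,
                 input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden), dropout = dropout,
                 layers = do.call(rbind, rows)),
            class = "cnn_arch_spec")
}

#' Build (initialize) a weak classifier
#'
#' Parameter initialization is deterministic in `seed` (He-normal weights
#' from a private RNG stream). The returned state carries the per-step loss
#' and close-test histories managed by the ensemble orchestrator.
#'
#' @param arch `"A"` or `"B"`, or a full [cnn_arch_spec()].
#' @param input_shape `c(height, width)`.
#' @param n_classes number of classes.
#' @param seed integer RNG seed.
#' @param ... passed to [cnn_arch_spec()].
#' @return object of class `classifier_state` with fields `spec`, `params`,
#'   `velocity`, `loss_history`, `score_history`, `epochs_executed`,
#'   `rng_seed`, `trained`.
#' @export
build_cnn <- function(arch, input_shape = c(64L, 128L), n_classes,
                      seed = 0L, ...) {
  spec <- if (inherits(arch, "cnn_arch_spec")) arch
          else cnn_arch_spec(arch, input_shape, n_classes, ...)
  params <- cpp_cnn_init(spec$filters, spec$ksize, spec$input_shape[1],
                         spec$input_shape[2], spec$hidden, spec$n_classes,
                         as.integer(seed))
  structure(list(spec = spec, params = params, velocity = NULL,
                 loss_history = numeric(0), score_history = numeric(0),
                 epochs_executed = integer(0),
                 rng_seed = as.integer(seed), step_count = 0L,
                 trained = FALSE),
            class = "classifier_state")
}

# images: list of matrices on the CNN input scale ([0, 1]). Each image is
# mean-centered: the DC level carries no identity information but dominates
# the activations of a randomly initialized conv stack, collapsing the
# per-image differences the classifier must learn from.
as_input_cube <- function(images, shape) {
  n <- length(images)
  x <- array(0, c(shape[1], shape[2], n))
  for (k in seq_len(n)) {
    m <- images[[k]]
    if (!all(dim(m) == shape)) m <- resize_bilinear(m, shape[1], shape[2])
    x[, , k] <- m - mean(m)
  }
  x
}

#' Train a weak classifier for a number of epochs
#'
#' Runs exactly `epochs` full passes of seeded mini-batch SGD. Histories
#' are not touched here; they are per training step and belong to the
#' orchestrator. Deterministic given `seed` (data order and dropout come
#' from a private RNG stream; the SGD momentum state persists across
#' calls).
#'
#' @param state a `classifier_state`.
#' @param images list of input matrices, values in `[0, 1]`.
#' @param labels integer class labels in `[0, n_classes)`.
#' @param epochs number of epochs (>= 1).
#' @param lr learning rate.
#' @param momentum SGD momentum.
#' @param batch_size mini-batch size (default `min(32, n_images)`).
#' @param seed integer seed for this call's shuffling/dropout stream.
#' @return updated `classifier_state`; attribute `final_loss` holds the
#'   deterministic post-training mean cross-entropy on `images`.
#' @export
train_epochs <- function(state, images, labels, epochs, lr = 0.01,
                         momentum = 0.9, batch_size = NULL, seed = 0L) {
  stopifnot(inherits(state, "classifier_state"))
  if (epochs < 1) stopf("epochs must be >= 1; got %s", epochs)
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= state$spec$n_classes))
    stopf("labels must lie in [0, %d)", state$spec$n_classes)
  if (length(images) != length(labels))
    stopf("images and labels differ in length")
  if (is.null(batch_size)) batch_size <- min(32L, length(images))
  x <- as_input_cube(images, state$spec$input_shape)
  fit <- cpp_cnn_train(state$params, x, labels, as.integer(epochs), lr,
                       momentum, as.integer(batch_size),
                       state$spec$dropout, as.integer(seed),
                       state$velocity)
  state$params <- fit$params
  state$velocity <- fit$velocity
  state$trained <- TRUE
  attr(state, "final_loss") <- fit$final_loss
  attr(state, "epoch_loss") <- fit$epoch_loss
  state
}

#' Class probabilities for a batch of images
#'
#' @param state a `classifier_state`.
#' @param images list of input matrices in `[0, 1]`.
#' @return `n_images` x `n_classes` matrix of softmax probabilities.
#' @export
predict_proba <- function(state, images) {
  stopifnot(inherits(state, "classifier_state"))
  x <- as_input_cube(images, state$spec$input_shape)
  cpp_cnn_predict(state$params, x)
}

#' Close test: accuracy on the training set
#'
#' Under SSPP there is no validation split, so classifier quality is
#' measured on the training images themselves ("close test"): the fraction
#' whose argmax prediction equals the label.
#'
#' @param state a `classifier_state`.
#' @param images list of input matrices in `[0, 1]`.
#' @param labels integer labels in `[0, n_classes)`.
#' @return scalar score in `[0, 1]`.
#' @export
close_test <- function(state, images, labels) {
  if (length(images) == 0) stopf("close test needs a nonempty set")
  p <- predict_proba(state, images)
  pred <- max.col(p, ties.method = "first") - 1L
  mean(pred == as.integer(labels))
}

#' Mean cross-entropy loss on a set
#'
#' @param state a `classifier_state`.
#' @param images list of input matrices in `[0, 1]`.
#' @param labels integer labels.
#' @return scalar mean categorical cross-entropy.
#' @export
cnn_loss <- function(state, images, labels) {
  x <- as_input_cube(images, state$spec$input_shape)
  cpp_cnn_loss(state$params, x, as.integer(labels))
}

#' @export
print.classifier_state <- function(x, ...) {
  cat(sprintf(
    "<classifier_state> arch %s, input %dx%d, %d classes, %d step(s)\n",
    x$spec$arch, x$spec$input_shape[1], x$spec$input_shape[2],
    x$spec$n_classes, x$step_count))
  invisible(x)
}
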