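#' Ensemble training schedules and gated weighted voting
#'
#' Training runs in `K` steps of `P` epochs per weak classifier (total
#' `R = K * P` own-map epochs). Three regimes are supported:
#' \describe{
#'   \item{basic}{each classifier trains independently on its own map;}
#'   \item{shared}{after its own `P` epochs, a classifier is fine-tuned for
#'     a few epochs on each sufficiently similar feature map
#'     (`Ec = 2 * floor(P/4 * St) - 1`, clamped at 0), visiting maps in
#'     decreasing similarity order;}
#'   \item{full}{shared learning plus loss-driven learning-speed
#'     adjustment: the own-map epoch count of step `u` is
#'     `floor(sigmoid(L[u-1]) * P)` (at least 1), so classifiers that have
#'     already converged slow down.}
#' }
#' After every step the ensemble voting weights are refreshed from the
#' close-test scores (positive evidence `E+`) and losses (negative
#' evidence `E-`); classifiers with close-test score above 0.5 are gated
#' in, weighted by `|E+ - E-|` renormalized over the gated set.
#'
#' @name ensemble_training
NULL

#' Shared-learning epoch count for one feature-map pair
#'
#' `Ec = 2 * floor((P/4) * St) - 1`, clamped below at 0; a clamped pair is
#' skipped entirely, which is how low-similarity pairs are excluded
#' without a separate threshold.
#'
#' @param st feature-map similarity in (0, 1].
#' @param p_epochs epochs per training step (>= 1).
#' @return integer epoch count >= 0 (odd when positive).
#' @export
shared_epochs <- function(st, p_epochs) {
  if (any(st <= 0 | st > 1)) stopf("St must lie in (0, 1]")
  if (p_epochs < 1) stopf("P must be >= 1")
  pmax(0, 2 * floor(p_epochs / 4 * st) - 1)
}

#' Learning-speed factor from the previous step's loss
#'
#' `alpha = 1 / (1 + exp(-L))`: 0.5 at zero loss, approaching 1 for large
#' losses, so well-trained classifiers take fewer epochs next step.
#'
#' @param l_prev loss value (>= 0).
#' @return alpha in [0.5, 1).
#' @export
speed_alpha <- function(l_prev) {
  if (any(l_prev < 0)) stopf("loss must be >= 0")
  1 / (1 + exp(-l_prev))
}

#' Epochs for the next training step
#'
#' `p = floor(alpha * P)`, floored to 1 so every classifier keeps training.
#'
#' @param alpha speed factor in (0, 1].
#' @param p_epochs nominal epochs per step (>= 1).
#' @return integer epoch count >= 1.
#' @export
step_epochs <- function(alpha, p_epochs) {
  p <- floor(alpha * p_epochs)
  ifelse(p < 1, 1L, as.integer(p))
}

#' Positive ensemble evidence from close-test scores
#'
#' Normalized logistic sigmoids of the scores; sums to 1.
#'
#' @param scores close-test scores in [0, 1].
#' @return vector `E+` summing to 1.
#' @export
pos_weight <- function(scores) {
  if (length(scores) == 0) stopf("empty score vector")
  if (any(scores < 0 | scores > 1)) stopf("scores must lie in [0, 1]")
  s <- 1 / (1 + exp(-scores))
  s / sum(s)
}

#' Negative ensemble evidence from losses
#'
#' Normalized logistic sigmoids of the per-classifier losses; sums to 1.
#'
#' @param losses loss values (>= 0).
#' @return vector `E-` summing to 1.
#' @export
neg_weight <- function(losses) {
  if (length(losses) == 0) stopf("empty loss vector")
  if (any(losses < 0)) stopf("losses must be >= 0")
  s <- 1 / (1 + exp(-losses))
  s / sum(s)
}

#' Gated ensemble voting weights
#'
#' Classifiers with close-test score above `gate_threshold` join the
#' ensemble with weight proportional to `|E+ - E-|`, renormalized over the
#' gated set; the rest get weight 0. If no classifier passes the gate (or
#' every gated `|E+ - E-|` is zero) the weights fall back to uniform over
#' all classifiers and `fallback = TRUE` is flagged.
#'
#' Gating on the raw close-test score follows the method's prose; gating
#' on `E+ >= 0.5` would be unreachable for six normalized weights.
#'
#' @param e_plus,e_minus evidence vectors from [pos_weight()] /
#'   [neg_weight()].
#' @param scores close-test scores used for the gate.
#' @param gate_threshold score threshold (default 0.5).
#' @return list with `w` (weights summing to 1), `gate` (logical mask),
#'   `fallback` (logical).
#' @export
ensemble_weights <- function(e_plus, e_minus, scores,
                             gate_threshold = 0.5) {
  stopifnot(length(e_plus) == length(e_minus),
            length(e_plus) == length(scores))
  gate <- scores > gate_threshold
  d <- abs(e_plus - e_minus)
  w <- numeric(length(scores))
  fallback <- FALSE
  if (!any(gate) || sum(d[gate]) < .Machine$double.eps) {
    w[] <- 1 / length(scores)
    fallback <- TRUE
  } else {
    w[gate] <- d[gate] / sum(d[gate])
  }
  list(w = w, gate = gate, fallback = fallback)
}

#' Configuration for ensemble training
#'
#' @param K_steps number of training steps.
#' @param P_epochs nominal epochs per step.
#' @param R total own-map epochs; must equal `K_steps * P_epochs`.
#' @param lr,momentum,batch_size SGD hyperparameters.
#' @param hidden dense-stage width of every weak classifier.
#' @param input_shape CNN input size `c(h, w)`; all maps are resized to it.
#' @param seed master seed: per-classifier and per-step streams derive
#'   from it.
#' @param gate_threshold close-test gate for the ensemble.
#' @param late_kernel5 use the 5x5 late-kernel architecture variant.
#' @param lbp,bank,fsim,pc feature-map and similarity parameter blocks.
#' @return object of class `ensemble_config`.
#' @export
ensemble_config <- function(K_steps = 50L, P_epochs = 4L,
                            R = K_steps * P_epochs, lr = 0.01,
                            momentum = 0.9, batch_size = NULL,
                            hidden = 128L, input_shape = c(64L, 128L),
                            seed = 0L, gate_threshold = 0.5,
                            late_kernel5 = FALSE, lbp = lbp_params(),
                            bank = gabor_bank(), fsim = fsim_params(),
                            pc = pc_params()) {
  if (R != K_steps * P_epochs)
    stopf("inconsistent schedule: R = %s but K * P = %s", R,
          K_steps * P_epochs)
  if (K_steps < 1 || P_epochs < 1) stopf("K and P must be >= 1")
  structure(list(K_steps = as.integer(K_steps),
                 P_epochs = as.integer(P_epochs), R = as.integer(R),
                 lr = lr, momentum = momentum, batch_size = batch_size,
                 hidden = as.integer(hidden),
                 input_shape = as.integer(input_shape),
                 seed = as.integer(seed), gate_threshold = gate_threshold,
                 late_kernel5 = late_kernel5, lbp = lbp, bank = bank,
                 fsim = fsim, pc = pc),
            class = "ensemble_config")
}

# CNN inputs (list over training images) for feature map i.
map_inputs <- function(map_sets, i) {
  lapply(map_sets, map_as_cnn_input, i = i)
}

train_ensemble <- function(dataset, config,
                           regime = c("basic", "shared", "full")) {
  regime <- match.arg(regime)
  stopifnot(inherits(dataset, "vein_dataset"),
            inherits(config, "ensemble_config"))
  split <- sspp_split(dataset)
  train <- split$train
  if (length(train$samples) == 0)
    stopf("SSPP split yields an empty training set")
  labels <- vapply(train$samples, `[[`, 0, "class_id")
  if (!setequal(labels, seq_len(dataset$n_classes) - 1L))
    stopf("training set must contain exactly one sample per class")
  map_sets <- dataset_feature_maps(train, config$lbp, config$bank)

  st <- NULL
  ec <- matrix(0L, 6, 6)
  if (regime != "basic") {
    st <- similarity_matrix(map_sets, config$fsim, config$pc)
    for (i in 1:6) for (j in 1:6)
      if (i != j) ec[i, j] <- shared_epochs(st$values[i, j],
                                            config$P_epochs)
  }

  inputs <- lapply(1:6, function(i) map_inputs(map_sets, i))
  classifiers <- lapply(1:6, function(i)
    build_cnn(if (i <= 2) "A" else "B", config$input_shape,
              dataset$n_classes, seed = derive_seed(config$seed, i),
              hidden = config$hidden, late_kernel5 = config$late_kernel5))

  log_rows <- vector("list", config$K_steps * 6L)
  w <- rep(1 / 6, 6); gate <- rep(FALSE, 6); fallback <- TRUE
  e_plus <- e_minus <- rep(1 / 6, 6)

  for (u in seq_len(config$K_steps)) {
    for (i in 1:6) {
      state <- classifiers[[i]]
      if (regime == "full" && u > 1L) {
        p_own <- step_epochs(speed_alpha(state$loss_history[u - 1L]),
                             config$P_epochs)
      } else p_own <- config$P_epochs
      state <- train_epochs(state, inputs[[i]], labels, p_own,
                            lr = config$lr, momentum = config$momentum,
                            batch_size = config$batch_size,
                            seed = derive_seed(state$rng_seed, u))
      shared_total <- 0L
      if (regime != "basic") {
        partners <- setdiff(order(st$values[i, ], decreasing = TRUE), i)
        for (j in partners) {
          if (ec[i, j] < 1L) next
          state <- train_epochs(state, inputs[[j]], labels, ec[i, j],
                                lr = config$lr, momentum = config$momentum,
                                batch_size = config$batch_size,
                                seed = derive_seed(state$rng_seed,
                                                   u * 100L + j))
          shared_total <- shared_total + ec[i, j]
        }
      }
      state$loss_history <- c(state$loss_history,
                              cnn_loss(state, inputs[[i]], labels))
      state$score_history <- c(state$score_history,
                               close_test(state, inputs[[i]], labels))
      state$epochs_executed <- c(state$epochs_executed, p_own)
      state$step_count <- u
      classifiers[[i]] <- state
      log_rows[[(u - 1L) * 6L + i]] <- data.frame(
        step = u, classifier = i,
        loss = state$loss_history[u], score = state$score_history[u],
        epochs_own = p_own, epochs_shared = shared_total)
    }
    scores_u <- vapply(classifiers, function(s) s$score_history[u], 0)
    losses_u <- vapply(classifiers, function(s) s$loss_history[u], 0)
    e_plus <- pos_weight(scores_u)
    e_minus <- neg_weight(losses_u)
    ew <- ensemble_weights(e_plus, e_minus, scores_u,
                           config$gate_threshold)
    w <- ew$w; gate <- ew$gate; fallback <- ew$fallback
    for (i in 1:6) {
      r <- (u - 1L) * 6L + i
      log_rows[[r]]$e_plus <- e_plus[i]
      log_rows[[r]]$e_minus <- e_minus[i]
      log_rows[[r]]$w <- w[i]
      log_rows[[r]]$gate <- gate[i]
      log_rows[[r]]$fallback <- fallback
    }
  }
  if (fallback)
    warning("no classifier passed the close-test gate; ",
            "using uniform ensemble weights", call. = FALSE)

  structure(list(classifiers = classifiers, w = w, gate = gate,
                 fallback = fallback, e_plus = e_plus, e_minus = e_minus,
                 st = st, ec = ec, regime = regime, config = config,
                 n_classes = dataset$n_classes,
                 history = do.call(rbind, log_rows), trained = TRUE),
            class = "ensemble_model")
}

#' Train the basic ensemble (independent weak classifiers)
#'
#' @param dataset a `vein_dataset` with SSPP structure (the split is taken
#'   internally: session 1 sample 1 trains, sessions >= 2 test).
#' @param config an [ensemble_config()].
#' @return object of class `ensemble_model`.
#' @export
train_basic <- function(dataset, config = ensemble_config()) {
  train_ensemble(dataset, config, "basic")
}

#' Train with FSIM-driven shared learning
#'
#' @inheritParams train_basic
#' @return an `ensemble_model`.
#' @export
train_shared <- function(dataset, config = ensemble_config()) {
  train_ensemble(dataset, config, "shared")
}

#' Train with shared learning and learning-speed adjustment
#'
#' @inheritParams train_basic
#' @return an `ensemble_model`.
#' @export
train_full <- function(dataset, config = ensemble_config()) {
  train_ensemble(dataset, config, "full")
}

# Per-classifier probability matrices for a list of feature-map sets.
ensemble_probas <- function(model, map_sets) {
  lapply(1:6, function(i)
    predict_proba(model$classifiers[[i]],
                  lapply(map_sets, map_as_cnn_input, i = i)))
}

#' Predict the identity of a probe image
#'
#' Builds the six feature maps of the probe, runs every positively
#' weighted classifier on its own map and combines the per-class
#' probabilities as `sum_i W_i p_i(class)`. Ties break to the lowest
#' class index.
#'
#' @param object a trained `ensemble_model`.
#' @param image numeric matrix (8-bit gray levels).
#' @param ... unused.
#' @return list with `class_id` and `probs` (length `n_classes`, sums
#'   to 1).
#' @export
predict.ensemble_model <- function(object, image, ...) {
  if (!isTRUE(object$trained)) stopf("model is not trained")
  assert_gray(image)
  probas <- ensemble_probas(
    object,
    list(build_feature_maps(image, object$config$lbp, object$config$bank)))
  p <- Reduce(`+`, lapply(1:6, function(i) object$w[i] * probas[[i]][1, ]))
  list(class_id = which.max(p) - 1L, probs = p)
}

#' Evaluate identification accuracy on a test set
#'
#' @param model a trained `ensemble_model`.
#' @param test_set a `vein_dataset` of probe samples.
#' @return list with `accuracy`, `per_classifier` (length-6 accuracy
#'   vector) and `records` (one row per probe: path, true and predicted
#'   class, top ensemble probability).
#' @export
evaluate <- function(model, test_set) {
  stopifnot(inherits(model, "ensemble_model"),
            inherits(test_set, "vein_dataset"))
  if (length(test_set$samples) == 0) stopf("test set is empty")
  truth <- vapply(test_set$samples, `[[`, 0, "class_id")
  probas <- ensemble_probas(
    model, dataset_feature_maps(test_set, model$config$lbp,
                                model$config$bank))
  comb <- Reduce(`+`, lapply(1:6, function(i) model$w[i] * probas[[i]]))
  pred <- max.col(comb, ties.method = "first") - 1L
  per_cls <- vapply(1:6, function(i)
    mean(max.col(probas[[i]], ties.method = "first") - 1L == truth), 0)
  paths <- model_paths <- test_set$manifest$path
  records <- data.frame(
    sample_path = ifelse(is.na(paths), "", paths),
    class_id = vapply(test_set$samples, `[[`, 0, "class_id"),
    session = vapply(test_set$samples, `[[`, 0, "session"),
    sample = vapply(test_set$samples, `[[`, 0, "sample"),
    true_class = truth, predicted_class = pred,
    top_probability = comb[cbind(seq_along(pred), pred + 1L)],
    stringsAsFactors = FALSE)
  list(accuracy = mean(pred == truth), per_classifier = per_cls,
       records = records)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(
    "<ensemble_model> regime '%s', %d classes, %d step(s) of %d epoch(s)\n",
    x$regime, x$n_classes, x$config$K_steps, x$config$P_epochs))
  cat("weights:", paste(sprintf("%.3f", x$w), collapse = " "), "\n")
  invisible(x)
}
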