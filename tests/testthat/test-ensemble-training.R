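# End-to-end ensemble behavior at deliberately tiny scale (4 classes,
# 64x64 CNN inputs, K=2 steps of P=2 epochs) so the structural contracts
# can be asserted quickly; statistical behavior is covered by the
# acceptance suite.

tiny_config <- function(seed = 0, P = 2) {
  ensemble_config(K_steps = 2, P_epochs = P, seed = seed,
                  input_shape = c(64, 64))
}

test_that("config consistency is enforced", {
  expect_error(ensemble_config(K_steps = 3, P_epochs = 4, R = 10),
               "inconsistent")
  expect_error(ensemble_config(K_steps = 0), ">= 1")
})

test_that("basic training: histories, schedule and weight conservation", {
  ds <- fx_small_dataset()
  m <- suppressWarnings(train_basic(ds, tiny_config()))
  expect_s3_class(m, "ensemble_model")

  for (st in m$classifiers) {
    expect_length(st$loss_history, 2)   # one entry per step
    expect_length(st$score_history, 2)
    expect_true(all(st$score_history >= 0 & st$score_history <= 1))
    expect_true(all(st$loss_history >= 0))
    # schedule conservation: every step ran exactly P own-map epochs
    expect_equal(st$epochs_executed, rep(2L, 2))
  }
  h <- m$history
  for (u in unique(h$step)) {
    hu <- h[h$step == u, ]
    expect_equal(sum(hu$e_plus), 1, tolerance = 1e-9)
    expect_equal(sum(hu$e_minus), 1, tolerance = 1e-9)
    expect_equal(sum(hu$w), 1, tolerance = 1e-9)
  }
  expect_equal(sum(m$w), 1, tolerance = 1e-9)
})

test_that("with P below the sharing threshold, shared equals basic", {
  ds <- fx_small_dataset()
  # P = 2: Ec = 2*floor(0.5*St) - 1 <= -1 for any St < 1, clamped to 0
  mb <- suppressWarnings(train_basic(ds, tiny_config()))
  ms <- suppressWarnings(train_shared(ds, tiny_config()))
  expect_true(all(ms$ec[ms$st$values < 1 & !diag(6)] == 0))
  if (all(ms$ec == 0)) {
    for (i in 1:6)
      expect_equal(ms$classifiers[[i]]$loss_history,
                   mb$classifiers[[i]]$loss_history, tolerance = 1e-12)
  }
})

test_that("full regime adjusts per-step epochs by the previous loss", {
  ds <- fx_small_dataset()
  cfg <- ensemble_config(K_steps = 2, P_epochs = 8, seed = 1,
                         input_shape = c(64, 64))
  m <- suppressWarnings(train_full(ds, cfg))
  h <- m$history
  first <- h[h$step == 1, ]
  second <- h[h$step == 2, ]
  expect_true(all(first$epochs_own == 8))  # no loss history yet
  expect_equal(second$epochs_own,
               step_epochs(speed_alpha(first$loss), 8))
})

test_that("prediction is a convex combination and evaluation is sane", {
  ds <- fx_small_dataset()
  m <- suppressWarnings(train_basic(ds, tiny_config()))
  split <- sspp_split(ds)

  probe <- split$test$samples[[1]]$image
  pr <- predict(m, probe)
  expect_length(pr$probs, 4)
  expect_equal(sum(pr$probs), 1, tolerance = 1e-6)
  expect_equal(pr$class_id, which.max(pr$probs) - 1L)

  # single gated classifier: ensemble prediction equals that classifier's
  m1 <- m
  m1$w <- c(1, 0, 0, 0, 0, 0)
  pr1 <- predict(m1, probe)
  fm <- build_feature_maps(probe, m$config$lbp, m$config$bank)
  solo <- predict_proba(m$classifiers[[1]],
                        list(veinsemble:::map_as_cnn_input(fm, 1)))
  expect_equal(pr1$probs, as.numeric(solo), tolerance = 1e-12)

  ev <- evaluate(m, split$test)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_length(ev$per_classifier, 6)
  expect_equal(nrow(ev$records), length(split$test$samples))
  expect_named(ev$records,
               c("sample_path", "class_id", "session", "sample",
                 "true_class", "predicted_class", "top_probability"))

  # permutation invariance of the accuracy
  perm <- split$test
  idx <- rev(seq_along(perm$samples))
  perm$samples <- perm$samples[idx]
  perm$manifest <- perm$manifest[idx, , drop = FALSE]
  attr(perm, "feature_maps") <- attr(split$test, "feature_maps")[idx]
  expect_equal(evaluate(m, perm)$accuracy, ev$accuracy)

  empty <- split$test
  empty$samples <- list()
  empty$manifest <- empty$manifest[0, , drop = FALSE]
  attr(empty, "feature_maps") <- NULL
  expect_error(evaluate(m, empty), "empty")
})

test_that("training is reproducible under the master seed", {
  ds <- fx_small_dataset()
  m1 <- suppressWarnings(train_basic(ds, tiny_config(seed = 4)))
  m2 <- suppressWarnings(train_basic(ds, tiny_config(seed = 4)))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$w, m2$w)
})
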