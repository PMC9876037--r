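test_that("architecture specs conform to the parameter tables", {
  sA <- cnn_arch_spec("A", c(64, 128), n_classes = 10)
  sB <- cnn_arch_spec("B", c(64, 128), n_classes = 10)
  convA <- sA$layers[sA$layers$type == "conv", ]
  convB <- sB$layers[sB$layers$type == "conv", ]
  expect_equal(convA$n_filters, c(64, 64, 64, 128, 256))
  expect_equal(convB$n_filters, c(64, 64, 64, 128, 128, 256))
  expect_true(all(convA$kernel == "2x2"))
  expect_true(all(convA$stride == "1x1"))
  expect_equal(sum(sA$layers$type == "maxpool"), 5)
  expect_equal(sum(sB$layers$type == "maxpool"), 6)
  # dropout 0.5 on the ReLU stage immediately before the softmax
  expect_equal(sA$layers$dropout[sA$layers$type == "relu-dropout"], 0.5)
  expect_equal(utils::tail(sA$layers$type, 2), c("relu-dropout", "softmax"))

  s5 <- cnn_arch_spec("B", c(64, 128), n_classes = 10, late_kernel5 = TRUE)
  expect_equal(s5$ksize, c(2L, 2L, 2L, 2L, 5L, 5L))
})

test_that("build_cnn initialization, forward pass and size guards", {
  st <- build_cnn("A", c(64, 128), n_classes = 7, seed = 1)
  set.seed(99)
  img <- list(matrix(runif(64 * 128), 64, 128))
  p <- predict_proba(st, img)
  expect_equal(dim(p), c(1L, 7L))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))

  st2 <- build_cnn("A", c(64, 128), n_classes = 7, seed = 1)
  expect_identical(st$params$conv_w, st2$params$conv_w)
  st3 <- build_cnn("A", c(64, 128), n_classes = 7, seed = 2)
  expect_false(identical(st$params$conv_w[[1]], st3$params$conv_w[[1]]))

  expect_error(build_cnn("B", c(16, 16), n_classes = 5), "at least 64x64")
})

test_that("training contracts: preconditions and determinism", {
  set.seed(42)
  imgs <- lapply(1:3, function(i) matrix(runif(32 * 64), 32, 64))
  st <- build_cnn("A", c(32, 64), n_classes = 3, seed = 5)
  expect_error(train_epochs(st, imgs, 0:2, epochs = 0), "epochs")
  expect_error(train_epochs(st, imgs, c(0, 1, 5), epochs = 1), "labels")

  a <- train_epochs(build_cnn("A", c(32, 64), 3, seed = 5), imgs, 0:2,
                    epochs = 2, seed = 9)
  b <- train_epochs(build_cnn("A", c(32, 64), 3, seed = 5), imgs, 0:2,
                    epochs = 2, seed = 9)
  expect_identical(attr(a, "final_loss"), attr(b, "final_loss"))
  expect_identical(a$params$fc2_w, b$params$fc2_w)
})

test_that("a weak classifier memorizes one image per class", {
  set.seed(17)
  imgs <- lapply(1:5, function(i) {
    m <- matrix(runif(32 * 64, 0.3, 0.7), 32, 64)
    m[, ((i - 1) * 12 + 1):((i - 1) * 12 + 8)] <- 0.05  # class-specific band
    m
  })
  st <- build_cnn("A", c(32, 64), n_classes = 5, seed = 3)
  score <- 0
  for (k in 1:12) {
    st <- train_epochs(st, imgs, 0:4, epochs = 5, seed = 20 + k)
    score <- close_test(st, imgs, 0:4)
    if (score == 1) break
  }
  expect_equal(score, 1)
  expect_lt(attr(st, "final_loss"), 1)
})

test_that("close test bounds and chance level when untrained", {
  set.seed(31)
  imgs <- lapply(1:5, function(i) matrix(runif(32 * 64), 32, 64))
  scores <- vapply(1:10, function(s)
    close_test(build_cnn("A", c(32, 64), 5, seed = s), imgs, 0:4), 0)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_gt(mean(scores), 0.0)
  expect_lt(mean(scores), 0.6)  # near 1/C = 0.2 in expectation
  expect_error(close_test(build_cnn("A", c(32, 64), 5, 1), list(), integer(0)),
               "nonempty")
})
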