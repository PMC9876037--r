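test_that("LBP matches the exhaustive bitwise oracle on random images", {
  set.seed(101)
  for (rep in 1:20) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_identical(compute_lbp(img), oracle_lbp(img))
  }
})

test_that("LBP analytic cases and invariances", {
  expect_true(all(compute_lbp(matrix(7, 5, 5)) == 255))  # s(0) = 1

  img <- matrix(0, 5, 5); img[3, 3] <- 10
  expect_equal(compute_lbp(img)[3, 3], 0)  # center brighter than all

  patch <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3, byrow = TRUE)
  expect_identical(compute_lbp(patch), oracle_lbp(patch))

  # invariant to adding a constant (differences unchanged)
  set.seed(7)
  img <- matrix(sample(0:200, 100, replace = TRUE), 10, 10)
  expect_identical(compute_lbp(img), compute_lbp(img + 17))

  expect_error(compute_lbp(matrix(1, 2, 2)), "3x3")
  expect_error(lbp_params(neighbors = 16), "8-neighbor")
})

test_that("Gabor kernel matches pointwise evaluation of the formula", {
  p <- gabor_params(lambda = pi / 2, theta = 0, kernel_size = 7)
  expect_equal(gabor_kernel(p)[4, 4], 1)  # psi = 0 at the origin

  # theta = pi/2 kernel is the theta = 0 kernel rotated by 90 degrees
  k0 <- gabor_kernel(gabor_params(lambda = 2, theta = 0, kernel_size = 9))
  k90 <- gabor_kernel(gabor_params(lambda = 2, theta = pi / 2,
                                   kernel_size = 9))
  rot90 <- t(k0)[9:1, ]  # counter-clockwise quarter turn
  expect_lt(max(abs(k90 - rot90)), 1e-12)

  for (th in c(0, pi / 4, 3 * pi / 4)) {
    prm <- gabor_params(lambda = pi / 2 * 11 / 7, theta = th,
                        kernel_size = 11)
    oracle <- oracle_gabor_kernel(prm$lambda, th, 0, prm$delta, 0.5, 11)
    expect_lt(max(abs(gabor_kernel(prm) - oracle)), 1e-12)
  }
  expect_error(gabor_params(lambda = 2, kernel_size = 8), "odd")
  expect_error(gabor_params(lambda = -1), "lambda")
})

test_that("fused Gabor feature map behaves as specified", {
  expect_true(all(gabor_feature(matrix(100, 32, 32)) == 0))  # degenerate

  s <- fx_samples()
  f <- gabor_feature(s$a1$image)
  expect_true(all(f >= 0 & f <= 255))
  expect_true(all(f == round(f)))

  # a dark diagonal line responds most along the 45-degree orientation
  img <- matrix(200, 33, 33)
  for (i in 1:33) img[i, i] <- 40
  bank <- gabor_bank()
  resp <- veinsemble:::gabor_responses(img, bank)
  th <- vapply(bank$members, `[[`, 0, "theta")
  # image row = y down, so the visual diagonal i==j is the 135-degree
  # direction in the x/y convention of the kernels
  e135 <- mean(vapply(resp[th == 3 * pi / 4], function(r)
    mean(abs(r[cbind(5:29, 5:29)])), 0))
  e45 <- mean(vapply(resp[th == pi / 4], function(r)
    mean(abs(r[cbind(5:29, 5:29)])), 0))
  expect_gt(e135, e45)

  expect_error(gabor_bank(scales = integer(0)), "at least one")
})

test_that("vein segmentation recovers ground truth reasonably", {
  s <- fx_samples()
  for (r in s) {
    seg <- segment_veins(r$image)
    expect_true(all(seg %in% c(0, 1)))
    dice <- 2 * sum(seg & r$mask) / (sum(seg) + sum(r$mask))
    expect_gte(dice, 0.5)
  }
  expect_true(all(segment_veins(matrix(128, 64, 64)) == 0))
})

test_that("build_feature_maps composes the six maps coherently", {
  s <- fx_samples()
  fm <- build_feature_maps(s$a1$image)
  expect_s3_class(fm, "feature_map_set")
  expect_length(fm$maps, 6)
  for (m in fm$maps) expect_equal(dim(m), dim(s$a1$image))

  expect_identical(fm$maps[[1]], s$a1$image)
  expect_true(all(fm$maps[[2]] %in% c(0, 1)))
  expect_identical(fm$maps[[3]], compute_lbp(s$a1$image))
  expect_identical(fm$maps[[4]], compute_lbp(fm$maps[[2]] * 255))
  fg <- mean(fm$maps[[2]])
  expect_gt(fg, 0); expect_lt(fg, 0.5)

  expect_identical(fm, build_feature_maps(s$a1$image))  # deterministic
})
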