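# Scheduler and voting-weight arithmetic (shared epochs, speed factor,
# per-step epochs, E+/E-, gated weights).

test_that("shared_epochs follows the formula with the zero clamp", {
  expect_equal(shared_epochs(1, 8), 3)      # 2*floor(2)-1
  expect_equal(shared_epochs(0.3, 8), 0)    # raw -1, clamped
  expect_equal(shared_epochs(0.64, 20), 5)  # 2*floor(3.2)-1
  expect_equal(shared_epochs(0.5, 8), 1)
  expect_equal(shared_epochs(0.99, 4), 0)   # P=4 shares only at St=1
  expect_equal(shared_epochs(1, 4), 1)
  # positive values are always odd
  for (st in seq(0.05, 1, by = 0.05)) for (p in c(4, 8, 12, 20)) {
    ec <- shared_epochs(st, p)
    expect_true(ec == 0 || ec %% 2 == 1)
    expect_equal(ec, max(0, 2 * floor(p / 4 * st) - 1))
  }
  expect_error(shared_epochs(0, 8), "\\(0, 1\\]")
  expect_error(shared_epochs(1.2, 8), "\\(0, 1\\]")
})

test_that("speed_alpha is the logistic sigmoid of the loss", {
  expect_equal(speed_alpha(0), 0.5)
  expect_equal(speed_alpha(1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(speed_alpha(10), 1 / (1 + exp(-10)), tolerance = 1e-12)
  expect_true(all(diff(speed_alpha(seq(0, 5, 0.5))) > 0))  # monotone
  expect_error(speed_alpha(-0.1), ">= 0")
})

test_that("step_epochs floors with the minimum-one branch", {
  expect_equal(step_epochs(0.5, 10), 5)
  expect_equal(step_epochs(0.6, 1), 1)   # floor(0.6) < 1 branch
  expect_equal(step_epochs(1 / (1 + exp(-1)), 10), 7)
  expect_equal(step_epochs(0.999, 8), 7)
  expect_equal(step_epochs(1, 8), 8)
})

test_that("E+ and E- are normalized sigmoids", {
  expect_equal(pos_weight(rep(0.7, 6)), rep(1 / 6, 6))
  s <- c(0.9, 0.1)
  expect_equal(pos_weight(s),
               (1 / (1 + exp(-s))) / sum(1 / (1 + exp(-s))),
               tolerance = 1e-12)
  l <- c(2.0, 0.5)
  expect_equal(neg_weight(l),
               (1 / (1 + exp(-l))) / sum(1 / (1 + exp(-l))),
               tolerance = 1e-12)
  set.seed(8)
  for (k in 1:20) {
    sc <- runif(6); lo <- rexp(6)
    expect_equal(sum(pos_weight(sc)), 1, tolerance = 1e-12)
    expect_equal(sum(neg_weight(lo)), 1, tolerance = 1e-12)
  }
  expect_error(pos_weight(numeric(0)), "empty")
  expect_error(pos_weight(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(neg_weight(c(-1, 0)), ">= 0")
})

test_that("gated ensemble weights renormalize over the gate", {
  # exactly one classifier gated: it takes all the weight
  ew <- ensemble_weights(c(0.4, 0.3, 0.3), c(0.2, 0.4, 0.4),
                         scores = c(0.9, 0.2, 0.3))
  expect_equal(ew$w, c(1, 0, 0))
  expect_false(ew$fallback)

  # all gated with equal |E+ - E-|: uniform
  ew <- ensemble_weights(rep(0.25, 4), rep(0.15, 4), scores = rep(0.8, 4))
  expect_equal(ew$w, rep(0.25, 4))

  # mixed case, cross-checked by hand arithmetic
  scores <- c(0.9, 0.6, 0.2)
  ep <- pos_weight(scores)
  em <- neg_weight(c(0.5, 1.5, 2.5))
  ew <- ensemble_weights(ep, em, scores)
  expect_equal(which(ew$w > 0), c(1L, 2L))
  d <- abs(ep - em)
  expect_equal(ew$w[1:2], d[1:2] / sum(d[1:2]), tolerance = 1e-12)
  expect_equal(sum(ew$w), 1, tolerance = 1e-12)

  # nobody gated: uniform fallback flagged
  ew <- ensemble_weights(rep(1 / 6, 6), rep(1 / 6, 6), scores = rep(0.1, 6))
  expect_true(ew$fallback)
  expect_equal(ew$w, rep(1 / 6, 6))
})
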