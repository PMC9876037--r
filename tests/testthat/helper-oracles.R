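# Independent brute-force oracles, deliberately written without reusing any
# package internals.

# Exhaustive per-pixel LBP: explicit bit sum over the 8 neighbors at
# radius r on the replicate-padded image, p = 0 east, counter-clockwise.
oracle_lbp <- function(img, r = 1L) {
  h <- nrow(img); w <- ncol(img)
  at <- function(i, j) img[min(max(i, 1L), h), min(max(j, 1L), w)]
  dy <- c(0, -r, -r, -r, 0, r, r, r)
  dx <- c(r, r, 0, -r, -r, -r, 0, r)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    code <- 0
    for (p in 0:7) {
      gp <- at(i + dy[p + 1], j + dx[p + 1])
      if (gp - img[i, j] >= 0) code <- code + 2^p
    }
    out[i, j] <- code
  }
  out
}

# Pointwise scalar evaluation of the real Gabor function on the integer
# grid, double loop, no vectorization shared with the implementation.
oracle_gabor_kernel <- function(lambda, theta, psi, delta, gamma, size) {
  hsz <- (size - 1) / 2
  out <- matrix(0, size, size)
  for (row in 1:size) for (col in 1:size) {
    y <- row - hsz - 1
    x <- col - hsz - 1
    xp <- x * cos(theta) + y * sin(theta)
    yp <- -x * sin(theta) + y * cos(theta)
    out[row, col] <-
      exp(-(xp^2 + gamma^2 * yp^2) / (2 * delta^2)) *
      cos(2 * pi * xp / lambda + psi)
  }
  out
}

# Direct 'same' 3x3 cross-correlation with replicate borders (for checking
# the gradient operators).
oracle_conv3 <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  at <- function(i, j) img[min(max(i, 1L), h), min(max(j, 1L), w)]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1)
      acc <- acc + k[di + 2, dj + 2] * at(i + di, j + dj)
    out[i, j] <- acc
  }
  out
}
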