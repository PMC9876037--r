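# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All seeded package entry points go
# through this so library code never clobbers user RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Fold (seed, id) into a single reproducible 31-bit sub-seed.
derive_seed <- function(master_seed, id) {
  as.integer((as.double(master_seed) * 69061 + as.double(id) * 9973 + 1) %%
               2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_gray_matrix <- function(x) is.matrix(x) && is.numeric(x)

assert_gray <- function(x, what = "image") {
  if (!is_gray_matrix(x)) stopf("%s must be a numeric matrix", what)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Replicate-pad a matrix by `p` pixels on every side.
pad_replicate <- function(m, p) {
  ri <- c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p))
  ci <- c(rep(1L, p), seq_len(ncol(m)), rep(ncol(m), p))
  m[ri, ci, drop = FALSE]
}

# 2-D 'same' cross-correlation of image with a small kernel, replicate
# borders. Kernel dims must be odd. Direct sliding sums over kernel taps:
# fine for the 3x3..17x17 kernels used here.
conv2_same <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  p <- max(ph, pw)
  padded <- pad_replicate(img, p)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (dj in seq_len(kw)) {
    cj <- p - pw + dj
    for (di in seq_len(kh)) {
      kv <- kernel[di, dj]
      if (kv == 0) next
      ci <- p - ph + di
      out <- out + kv * padded[ci:(ci + h - 1L), cj:(cj + w - 1L)]
    }
  }
  out
}

# Separable Gaussian blur, replicate borders; sigma in pixels.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g <- g / sum(g)
  p <- pad_replicate(img, r)
  h <- nrow(img); w <- ncol(img)
  tmp <- matrix(0, h, ncol(p))
  for (i in seq_along(g))
    tmp <- tmp + g[i] * p[i:(i + h - 1L), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(g))
    out <- out + g[j] * tmp[, j:(j + w - 1L), drop = FALSE]
  out
}

# Local mean over a square window (odd side), replicate borders, via
# integral image on the padded matrix.
box_mean <- function(img, side) {
  r <- (side - 1L) %/% 2L
  p <- pad_replicate(img, r)
  ii <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  h <- nrow(img); w <- ncol(img)
  i1 <- seq_len(h); j1 <- seq_len(w)
  s <- ii[i1 + 2L * r + 1L, j1 + 2L * r + 1L, drop = FALSE] -
    ii[i1, j1 + 2L * r + 1L, drop = FALSE] -
    ii[i1 + 2L * r + 1L, j1, drop = FALSE] +
    ii[i1, j1, drop = FALSE]
  s / (side * side)
}

# Read/write 8-bit grayscale PNG as a numeric matrix in 0..255.
read_gray_png <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  a <- tryCatch(png::readPNG(path), error = function(e)
    stopf("cannot read image '%s': %s", path, conditionMessage(e)))
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  round(a * 255)
}

write_gray_png <- function(img, path) {
  png::writePNG(clamp01(img / 255), path)
  invisible(path)
}
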