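#' Phase congruency, FSIM and feature-map similarity
#'
#' Structural image similarity used to decide which feature maps share
#' knowledge during training. Phase congruency (PC) measures the local
#' significance of structure independently of contrast; FSIM combines a PC
#' similarity term and a gradient-magnitude similarity term, weighted by
#' the pointwise maximum PC. The dataset-level similarity St between two
#' feature-map types is the mean FSIM over maps derived from the same
#' source image, averaged over the training set.
#'
#' @name similarity
NULL

#' Phase congruency parameters
#'
#' The even/odd quadrature pairs are log-Gabor filters (4 scales x 4
#' orientations by default) with a raised Butterworth low-pass guard; no
#' noise-energy compensation is applied. The PC map is
#' `sum_o E_o / (epsilon + sum_{n,o} A_{n,o})`, clipped to `[0, 1]`, where
#' for each orientation `E = sqrt(F^2 + H^2)`, `F = sum_n e_n`,
#' `H = sum_n o_n` and `A_n = sqrt(e_n^2 + o_n^2)`.
#'
#' @param n_scales number of log-Gabor scales.
#' @param n_orientations number of filter orientations.
#' @param min_wavelength wavelength of the smallest-scale filter, pixels.
#' @param mult scale multiplier between successive filters.
#' @param sigma_onf ratio sigma/f0 of the log-Gabor radial spread.
#' @param d_theta_sigma angular spread divisor (theta_sigma =
#'   pi / n_orientations / d_theta_sigma).
#' @param epsilon small positive stabilizer in the PC denominator.
#' @return object of class `pc_params`.
#' @export
pc_params <- function(n_scales = 4L, n_orientations = 4L,
                      min_wavelength = 6, mult = 2, sigma_onf = 0.55,
                      d_theta_sigma = 1.2, epsilon = 1e-4) {
  if (epsilon <= 0) stopf("epsilon must be > 0")
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 min_wavelength = min_wavelength, mult = mult,
                 sigma_onf = sigma_onf, d_theta_sigma = d_theta_sigma,
                 epsilon = epsilon),
            class = "pc_params")
}

# Frequency-domain log-Gabor filter bank for an h x w image, cached per
# (h, w, params) in the package namespace.
.pc_cache <- new.env(parent = emptyenv())

pc_filter_bank <- function(h, w, params) {
  key <- paste(h, w, params$n_scales, params$n_orientations,
               params$min_wavelength, params$mult, params$sigma_onf,
               params$d_theta_sigma, sep = "_")
  if (!is.null(.pc_cache[[key]])) return(.pc_cache[[key]])
  fx <- (0:(w - 1)) / w; fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  fy <- (0:(h - 1)) / h; fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  FX <- matrix(rep(fx, each = h), h, w)
  FY <- matrix(rep(fy, times = w), h, w)
  radius <- sqrt(FX^2 + FY^2)
  radius[1, 1] <- 1
  theta <- atan2(-FY, FX)  # y axis points down in image coordinates
  lp <- 1 / (1 + (radius / 0.45)^30)  # Butterworth low-pass guard
  sintheta <- sin(theta); costheta <- cos(theta)
  theta_sigma <- pi / params$n_orientations / params$d_theta_sigma
  filters <- vector("list", params$n_orientations)
  for (o in seq_len(params$n_orientations)) {
    ang <- (o - 1) * pi / params$n_orientations
    ds <- sintheta * cos(ang) - costheta * sin(ang)
    dc <- costheta * cos(ang) + sintheta * sin(ang)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))
    sc <- vector("list", params$n_scales)
    for (n in seq_len(params$n_scales)) {
      wavelength <- params$min_wavelength * params$mult^(n - 1)
      f0 <- 1 / wavelength
      lg <- exp(-(log(radius / f0))^2 / (2 * log(params$sigma_onf)^2)) * lp
      lg[1, 1] <- 0
      sc[[n]] <- spread * lg
    }
    filters[[o]] <- sc
  }
  .pc_cache[[key]] <- filters
  filters
}

#' Phase congruency map
#'
#' @param image numeric matrix, at least 16x16.
#' @param params a [pc_params()] object.
#' @return matrix of PC values in `[0, 1]`.
#' @export
phase_congruency <- function(image, params = pc_params()) {
  assert_gray(image)
  if (nrow(image) < 16 || ncol(image) < 16)
    stopf("image must be at least 16x16 for phase congruency")
  h <- nrow(image); w <- ncol(image)
  filters <- pc_filter_bank(h, w, params)
  imfft <- stats::fft(image)
  energy <- matrix(0, h, w)
  amp_sum <- matrix(0, h, w)
  for (o in seq_along(filters)) {
    Fsum <- matrix(0, h, w); Hsum <- matrix(0, h, w)
    for (n in seq_along(filters[[o]])) {
      eo <- stats::fft(imfft * filters[[o]][[n]], inverse = TRUE) / (h * w)
      e <- Re(eo); od <- Im(eo)
      Fsum <- Fsum + e; Hsum <- Hsum + od
      amp_sum <- amp_sum + sqrt(e^2 + od^2)
    }
    energy <- energy + sqrt(Fsum^2 + Hsum^2)
  }
  pc <- energy / (params$epsilon + amp_sum)
  pmin(pmax(pc, 0), 1)
}

#' Gradient magnitude map
#'
#' `G = sqrt(Gh^2 + Gv^2)` with Scharr (default) or Sobel 3x3 operators,
#' carrying the conventional 1/16 (Scharr) and 1/4 (Sobel) scalings the
#' FSIM defaults (`T2 = 160`) were calibrated against.
#'
#' @param image numeric matrix.
#' @param operator `"scharr"` or `"sobel"`.
#' @return non-negative matrix of gradient magnitudes.
#' @export
gradient_magnitude <- function(image, operator = c("scharr", "sobel")) {
  assert_gray(image)
  operator <- match.arg(operator)
  kh <- switch(operator,
               scharr = matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3) / 16,
                               3, 3),
               sobel = matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1) / 4, 3, 3))
  gh <- conv2_same(image, kh)       # horizontal derivative (along x)
  gv <- conv2_same(image, t(kh))    # vertical derivative (along y)
  sqrt(gh^2 + gv^2)
}

#' FSIM parameters
#'
#' Defaults follow the established feature-similarity index practice for
#' 8-bit images: `T1 = 0.85` (PC term), `T2 = 160` (gradient term, scaled
#' to the gradient dynamic range), exponents `alpha = beta = 1`.
#'
#' @param T1,T2 positive stabilizing constants.
#' @param alpha,beta exponents weighting the PC and gradient terms.
#' @param gradient_operator passed to [gradient_magnitude()].
#' @return object of class `fsim_params`.
#' @export
fsim_params <- function(T1 = 0.85, T2 = 160, alpha = 1, beta = 1,
                        gradient_operator = "scharr") {
  if (T1 <= 0 || T2 <= 0) stopf("T1 and T2 must be > 0")
  if (alpha < 0 || beta < 0) stopf("alpha and beta must be >= 0")
  structure(list(T1 = T1, T2 = T2, alpha = alpha, beta = beta,
                 gradient_operator = gradient_operator),
            class = "fsim_params")
}

#' Feature similarity index (FSIM) of two grayscale images
#'
#' `FSIM = sum(S_PC^alpha * S_G^beta * PCm) / sum(PCm)` over the image
#' domain, with `PCm = pmax(PC1, PC2)` and the usual symmetric similarity
#' kernels for PC and gradient magnitude. Identical images give exactly 1.
#' If shapes differ and `resize = TRUE`, the second image is bilinearly
#' resized to the first's shape (guard path for misuse; maps compared in
#' this package are always co-registered).
#'
#' @param i1,i2 numeric matrices on a common intensity scale (0..255).
#' @param params an [fsim_params()] object.
#' @param pc a [pc_params()] object.
#' @param resize allow resizing `i2` on shape mismatch.
#' @param pc1,pc2 optional precomputed PC maps (cache hook).
#' @return scalar in (0, 1].
#' @export
fsim <- function(i1, i2, params = fsim_params(), pc = pc_params(),
                 resize = FALSE, pc1 = NULL, pc2 = NULL) {
  assert_gray(i1); assert_gray(i2)
  if (!all(dim(i1) == dim(i2))) {
    if (!resize) stopf("images differ in shape (%dx%d vs %dx%d)",
                       nrow(i1), ncol(i1), nrow(i2), ncol(i2))
    i2 <- resize_bilinear(i2, nrow(i1), ncol(i1))
    pc2 <- NULL
  }
  if (is.null(pc1)) pc1 <- phase_congruency(i1, pc)
  if (is.null(pc2)) pc2 <- phase_congruency(i2, pc)
  g1 <- gradient_magnitude(i1, params$gradient_operator)
  g2 <- gradient_magnitude(i2, params$gradient_operator)
  s_pc <- (2 * pc1 * pc2 + params$T1) / (pc1^2 + pc2^2 + params$T1)
  s_g <- (2 * g1 * g2 + params$T2) / (g1^2 + g2^2 + params$T2)
  sl <- s_pc^params$alpha * s_g^params$beta
  pcm <- pmax(pc1, pc2)
  denom <- sum(pcm)
  if (denom < .Machine$double.eps) return(mean(sl))
  sum(sl * pcm) / denom
}

resize_bilinear <- function(m, h, w) {
  yi <- seq(1, nrow(m), length.out = h)
  xi <- seq(1, ncol(m), length.out = w)
  y0 <- pmin(floor(yi), nrow(m) - 1L); x0 <- pmin(floor(xi), ncol(m) - 1L)
  fy <- yi - y0; fx <- xi - x0
  m00 <- m[y0, x0, drop = FALSE]; m10 <- m[y0 + 1, x0, drop = FALSE]
  m01 <- m[y0, x0 + 1, drop = FALSE]; m11 <- m[y0 + 1, x0 + 1, drop = FALSE]
  FY <- matrix(fy, h, w); FX <- matrix(fx, h, w, byrow = TRUE)
  m00 * (1 - FY) * (1 - FX) + m10 * FY * (1 - FX) +
    m01 * (1 - FY) * FX + m11 * FY * FX
}

# Feature-map sets for every image of a dataset (cached on the object).
dataset_feature_maps <- function(dataset, lbp = lbp_params(),
                                 bank = gabor_bank()) {
  if (!is.null(attr(dataset, "feature_maps")))
    return(attr(dataset, "feature_maps"))
  lapply(dataset$samples, function(s)
    build_feature_maps(s$image, lbp, bank))
}

#' Attach precomputed feature maps to a dataset
#'
#' Feature-map extraction is the most expensive deterministic part of the
#' pipeline; precomputing once lets several training regimes reuse it.
#'
#' @param dataset a `vein_dataset`.
#' @param lbp,bank feature-map parameters.
#' @return the dataset with a `feature_maps` attribute.
#' @export
precompute_feature_maps <- function(dataset, lbp = lbp_params(),
                                    bank = gabor_bank()) {
  attr(dataset, "feature_maps") <- dataset_feature_maps(dataset, lbp, bank)
  dataset
}

#' Dataset-level similarity of two feature-map types
#'
#' `St(Fi, Fj) = mean over training images of FSIM(map_i, map_j)`, both
#' maps derived from the same source image.
#'
#' @param map_sets list of `feature_map_set` objects (one per training
#'   image), e.g. from [precompute_feature_maps()].
#' @param i,j feature-map indices in 1..6.
#' @param params,pc FSIM / phase-congruency parameters.
#' @return scalar St in (0, 1].
#' @export
feature_map_similarity <- function(map_sets, i, j, params = fsim_params(),
                                   pc = pc_params()) {
  if (length(map_sets) == 0) stopf("need at least one training image")
  vals <- vapply(map_sets, function(ms)
    fsim(map_as_intensity(ms, i), map_as_intensity(ms, j), params, pc),
    0)
  mean(vals)
}

#' Similarity matrix of the six feature maps
#'
#' Symmetric 6x6 matrix of St values with unit diagonal, computed over the
#' training images. PC maps are computed once per (image, map) and reused
#' across the 15 pairs.
#'
#' @param train a `vein_dataset` (the SSPP training set) or a list of
#'   `feature_map_set` objects.
#' @param params,pc FSIM / phase-congruency parameters.
#' @param lbp,bank feature-map parameters (used if `train` is a dataset).
#' @return object of class `similarity_matrix`: list with `values` (6x6
#'   matrix, dimnames f1..f6) and `n`.
#' @export
similarity_matrix <- function(train, params = fsim_params(),
                              pc = pc_params(), lbp = lbp_params(),
                              bank = gabor_bank()) {
  map_sets <- if (inherits(train, "vein_dataset"))
    dataset_feature_maps(train, lbp, bank) else train
  if (length(map_sets) == 0) stopf("need at least one training image")
  n <- length(map_sets)
  vals <- diag(6)
  pcs <- lapply(map_sets, function(ms)
    lapply(1:6, function(k) phase_congruency(map_as_intensity(ms, k), pc)))
  for (i in 1:5) for (j in (i + 1):6) {
    s <- vapply(seq_len(n), function(t)
      fsim(map_as_intensity(map_sets[[t]], i),
           map_as_intensity(map_sets[[t]], j), params, pc,
           pc1 = pcs[[t]][[i]], pc2 = pcs[[t]][[j]]),
      0)
    vals[i, j] <- vals[j, i] <- mean(s)
  }
  dimnames(vals) <- list(paste0("f", 1:6), paste0("f", 1:6))
  structure(list(values = vals, n = n), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> St over %d training image(s)\n", x$n))
  print(round(x$values, 3))
  invisible(x)
}
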