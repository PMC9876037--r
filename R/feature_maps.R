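#' Feature maps for finger-vein images
#'
#' From one grayscale finger-vein image six co-registered feature maps are
#' derived: (1) the original image, (2) a binary vein segmentation,
#' (3) local binary patterns (LBP) of the original, (4) LBP of the
#' segmentation, (5) a Gabor texture map of the original and (6) a Gabor
#' texture map of the segmentation. Each map later feeds one weak CNN
#' classifier.
#'
#' @name feature_maps
NULL

#' LBP parameters
#'
#' Classic 8-neighbor local binary pattern. For each pixel the 8 neighbors
#' at radius `radius` on the 3x3 grid (no subpixel interpolation) are
#' compared against the center: code = sum over p of s(g_p - g_c) * 2^p
#' with s(x) = 1 iff x >= 0. Neighbor p = 0 sits due east and the ordering
#' proceeds counter-clockwise (in image coordinates, y growing downwards).
#'
#' @param radius neighborhood radius in pixels (>= 1).
#' @param neighbors number of neighbors; only 8 is supported.
#' @return object of class `lbp_params`.
#' @export
lbp_params <- function(radius = 1L, neighbors = 8L) {
  if (neighbors != 8L) stopf("only 8-neighbor LBP is supported")
  if (radius < 1) stopf("radius must be >= 1")
  structure(list(radius = as.integer(radius), neighbors = 8L),
            class = "lbp_params")
}

#' Compute the LBP code map
#'
#' Replicate padding keeps the output the same shape as the input so all
#' six feature maps stay co-registered.
#'
#' @param image numeric matrix.
#' @param params an [lbp_params()] object.
#' @return integer-valued matrix of codes in 0..255, same shape as `image`.
#' @export
compute_lbp <- function(image, params = lbp_params()) {
  assert_gray(image)
  if (nrow(image) < 3 || ncol(image) < 3)
    stopf("image must be at least 3x3 for LBP")
  r <- params$radius
  # p = 0 east, counter-clockwise: E, NE, N, NW, W, SW, S, SE
  dy <- c(0, -r, -r, -r, 0, r, r, r)
  dx <- c(r, r, 0, -r, -r, -r, 0, r)
  p <- pad_replicate(image, r)
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0, h, w)
  for (k in 1:8) {
    nb <- p[(1 + r + dy[k]):(h + r + dy[k]),
            (1 + r + dx[k]):(w + r + dx[k]), drop = FALSE]
    out <- out + (nb >= image) * 2^(k - 1)
  }
  out
}

#' Gabor kernel parameters
#'
#' Real part of the 2-D Gabor function
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 delta^2)) * cos(2 pi x' / lambda + psi)`
#' with `x' = x cos(theta) + y sin(theta)`,
#' `y' = -x sin(theta) + y cos(theta)`, evaluated on the integer grid
#' centered at (0, 0) (x = column offset, y = row offset).
#'
#' @param lambda wavelength of the cosine factor, pixels (> 0).
#' @param theta orientation, radians.
#' @param psi phase offset, radians.
#' @param delta standard deviation of the Gaussian envelope, pixels (> 0).
#' @param gamma spatial aspect ratio.
#' @param kernel_size odd side length in pixels.
#' @return object of class `gabor_params`.
#' @export
gabor_params <- function(lambda, theta = 0, psi = 0, delta = 0.56 * lambda,
                         gamma = 0.5, kernel_size = 7L) {
  if (lambda <= 0) stopf("lambda must be > 0")
  if (delta <= 0) stopf("delta must be > 0")
  if (kernel_size %% 2L == 0L)
    stopf("kernel_size must be odd; got %s", kernel_size)
  structure(list(lambda = lambda, theta = theta, psi = psi, delta = delta,
                 gamma = gamma, kernel_size = as.integer(kernel_size)),
            class = "gabor_params")
}

#' Build a real Gabor kernel
#'
#' @param params a [gabor_params()] object.
#' @return `kernel_size` x `kernel_size` numeric matrix; rows index y
#'   (downwards), columns index x.
#' @export
gabor_kernel <- function(params) {
  stopifnot(inherits(params, "gabor_params"))
  hsz <- (params$kernel_size - 1L) %/% 2L
  x <- matrix(rep(-hsz:hsz, each = params$kernel_size),
              params$kernel_size, params$kernel_size)
  y <- t(x)
  xp <- x * cos(params$theta) + y * sin(params$theta)
  yp <- -x * sin(params$theta) + y * cos(params$theta)
  exp(-(xp^2 + params$gamma^2 * yp^2) / (2 * params$delta^2)) *
    cos(2 * pi * xp / params$lambda + params$psi)
}

#' Gabor filter bank
#'
#' Default bank: six odd kernel sizes ("scales") 7, 9, 11, 13, 15, 17 and
#' four orientations 0, 45, 90, 135 degrees. The wavelength is tied to the
#' scale as `lambda = (pi/2) * scale / 7`, i.e. pi/2 at the base scale;
#' `delta = 0.56 lambda`, `gamma = 0.5`, `psi = 0`.
#'
#' @param scales odd kernel side lengths.
#' @param orientations orientations in radians.
#' @param lambda_base wavelength at the first scale.
#' @return object of class `gabor_bank`: list of [gabor_params()].
#' @export
gabor_bank <- function(scales = c(7L, 9L, 11L, 13L, 15L, 17L),
                       orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                       lambda_base = pi / 2) {
  if (length(scales) == 0 || length(orientations) == 0)
    stopf("bank must contain at least one scale and one orientation")
  members <- list()
  for (s in scales)
    for (th in orientations) {
      lam <- lambda_base * s / scales[1]
      members[[length(members) + 1L]] <-
        gabor_params(lambda = lam, theta = th, delta = 0.56 * lam,
                     gamma = 0.5, psi = 0, kernel_size = s)
    }
  structure(list(members = members, scales = scales,
                 orientations = orientations),
            class = "gabor_bank")
}

# Signed responses of every bank member (list of matrices).
gabor_responses <- function(image, bank) {
  lapply(bank$members, function(p) conv2_same(image, gabor_kernel(p)))
}

#' Fused Gabor feature map
#'
#' Per-pixel maximum of the absolute real-part responses over all bank
#' members, min-max normalized to 8-bit. A constant image (degenerate
#' normalization) maps to all zeros.
#'
#' @param image numeric matrix.
#' @param bank a [gabor_bank()].
#' @return numeric matrix with integer values in 0..255.
#' @export
gabor_feature <- function(image, bank = gabor_bank()) {
  assert_gray(image)
  if (length(image) == 0) stopf("image is empty")
  stopifnot(inherits(bank, "gabor_bank"))
  gabor_aggregate(gabor_responses(image, bank), dim(image))
}

gabor_aggregate <- function(resp, dims) {
  agg <- Reduce(pmax, lapply(resp, abs))
  rng <- range(agg)
  if (rng[2] - rng[1] < 1e-12) return(matrix(0, dims[1], dims[2]))
  round(255 * (agg - rng[1]) / (rng[2] - rng[1]))
}

#' Segment the vein network
#'
#' Deterministic classical stand-in for a learned vein segmenter. Veins are
#' darker than tissue, so a Gabor kernel centered on a vein responds
#' negatively: dark-line evidence is accumulated as the sum of
#' positive-rectified negated responses over the bank, smoothed with a
#' Gaussian (`smooth_sigma`), thresholded against a local mean (window
#' `window` plus `offset` standard deviations of the evidence map), cleaned
#' by a 3x3 morphological opening, and components smaller than
#' `min_component` pixels removed. The offset was tuned once on synthetic
#' data with ground-truth masks.
#'
#' @param image numeric matrix, 8-bit gray levels.
#' @param bank a [gabor_bank()] used for dark-line enhancement.
#' @param window local-threshold window side in pixels (odd).
#' @param offset threshold offset, in standard deviations of the enhanced
#'   map.
#' @param smooth_sigma Gaussian smoothing of the evidence map, pixels.
#' @param min_component minimum connected-component size kept, pixels.
#' @param responses optional precomputed bank responses (internal reuse).
#' @return binary 0/1 matrix, veins = 1.
#' @export
segment_veins <- function(image, bank = gabor_bank(), window = 15L,
                          offset = 0.05, smooth_sigma = 1.5,
                          min_component = 20L, responses = NULL) {
  assert_gray(image)
  resp <- if (is.null(responses)) gabor_responses(image, bank)
          else responses
  enh <- Reduce(`+`, lapply(resp, function(r) pmax(-r, 0)))
  enh <- gaussian_blur(enh, smooth_sigma)
  s <- stats::sd(enh)
  if (s < .Machine$double.eps) return(matrix(0, nrow(image), ncol(image)))
  fg <- enh > box_mean(enh, window) + offset * s
  fg <- morph_open(fg)
  fg <- remove_small_components(fg, min_component)
  fg * 1
}

# 3x3 binary erosion then dilation.
morph_open <- function(mask) {
  shift_all <- function(m, f) {
    p <- pad_replicate(m * 1, 1L)
    h <- nrow(m); w <- ncol(m)
    acc <- m * 1
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0) next
      acc <- f(acc, p[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)])
    }
    acc
  }
  er <- shift_all(mask, pmin) > 0
  shift_all(er, pmax) > 0
}

# Drop 4-connected foreground components below min_size pixels.
remove_small_components <- function(mask, min_size) {
  idx <- which(mask)
  if (length(idx) == 0) return(mask)
  h <- nrow(mask)
  pos <- match(idx, idx)
  id_of <- integer(length(mask)); id_of[idx] <- seq_along(idx)
  edges <- integer(0)
  for (d in c(1L, h)) {  # down and right neighbors
    a <- idx; b <- idx + d
    ok <- b <= length(mask) & id_of[pmin(b, length(mask))] > 0
    if (d == 1L) ok <- ok & (idx %% h != 0)  # no wrap across columns
    if (any(ok))
      edges <- c(edges, rbind(id_of[a[ok]], id_of[b[ok]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  keep <- comp$csize[comp$membership] >= min_size
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[idx[keep]] <- TRUE
  out
}

#' Build the six feature maps of one image
#'
#' Map 1: original; map 2: binary vein segmentation of the original;
#' map 3: LBP(original); map 4: LBP(map 2); map 5: Gabor(original);
#' map 6: Gabor(map 2). All maps share the input's shape. Maps are stored
#' on their natural scales (map 1 and 3-6 in 0..255, map 2 in \{0, 1\}).
#'
#' @param image numeric matrix (8-bit gray levels).
#' @param lbp an [lbp_params()] object.
#' @param bank a [gabor_bank()].
#' @param segmenter segmentation function `(image) -> binary matrix`;
#'   defaults to [segment_veins()]. A learned segmenter can be plugged in.
#' @return object of class `feature_map_set`: list `maps` of 6 matrices.
#' @export
build_feature_maps <- function(image, lbp = lbp_params(),
                               bank = gabor_bank(),
                               segmenter = segment_veins) {
  assert_gray(image)
  default_seg <- identical(segmenter, segment_veins)
  resp <- if (default_seg) gabor_responses(image, bank) else NULL
  seg <- if (default_seg) segment_veins(image, bank, responses = resp)
         else segmenter(image)
  maps <- list(
    image,
    seg,
    compute_lbp(image, lbp),
    compute_lbp(seg * 255, lbp),
    gabor_aggregate(if (is.null(resp)) gabor_responses(image, bank)
                    else resp, dim(image)),
    gabor_feature(seg * 255, bank))
  structure(list(maps = maps), class = "feature_map_set")
}

#' @export
print.feature_map_set <- function(x, ...) {
  d <- dim(x$maps[[1]])
  cat(sprintf("<feature_map_set> 6 maps, %dx%d\n", d[1], d[2]))
  invisible(x)
}

# Common 0..255 intensity scale for cross-map similarity.
map_as_intensity <- function(map_set, i) {
  m <- map_set$maps[[i]]
  if (i == 2L) m * 255 else m
}

# Normalized [0, 1] input for the CNNs.
map_as_cnn_input <- function(map_set, i) {
  m <- map_set$maps[[i]]
  if (i == 2L) m else m / 255
}
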