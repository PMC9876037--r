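#' Synthetic near-infrared finger-vein data
#'
#' Seeded generator of NIR-like finger-vein images with ground-truth vessel
#' masks. Each identity (finger class) owns a fixed random vessel skeleton;
#' samples are rendered across acquisition "sessions" that share a small
#' geometric/photometric drift, with per-sample sensor noise on top. The
#' single-sample-per-person (SSPP) protocol is emulated by training on the
#' first image of session 1 and testing on all later-session images.
#'
#' Vessels absorb NIR light, so vein pixels are always rendered darker than
#' the surrounding tissue; every sample satisfies
#' `mean(image[mask]) < mean(image[!mask])`.
#'
#' @name synthetic_data
NULL

#' Generate a finger template (fixed vessel skeleton for one class)
#'
#' A template is the identity: 3-6 smooth vessel branches drawn as jittered
#' random-walk control points smoothed by spline interpolation, each with a
#' radius of 1.5-3 px (scaled to the default 64x128 canvas so vessels stay
#' a minority of pixels, as in real NIR acquisitions). Identical `(class_id, master_seed)` pairs regenerate
#' bit-identical templates.
#'
#' @param class_id integer class label (>= 0).
#' @param master_seed integer master seed.
#' @param canvas_size `c(height, width)` in pixels, at least `c(32, 64)`.
#' @return object of class `finger_template` with fields `class_id`,
#'   `skeleton` (list of dense `cbind(y, x)` polylines), `vessel_radii`,
#'   `canvas_size`.
#' @export
generate_template <- function(class_id, master_seed,
                              canvas_size = c(64L, 128L)) {
  if (length(canvas_size) != 2L || canvas_size[1] < 32 || canvas_size[2] < 64)
    stopf("canvas_size must be at least (32, 64); got (%s, %s)",
          canvas_size[1], canvas_size[2])
  h <- as.integer(canvas_size[1]); w <- as.integer(canvas_size[2])
  with_seed(derive_seed(master_seed, class_id), {
    n_branch <- sample(3:6, 1L)
    margin <- 4
    skeleton <- vector("list", n_branch)
    radii <- numeric(n_branch)
    for (b in seq_len(n_branch)) {
      n_ctrl <- sample(5:8, 1L)
      xs <- seq(margin, w - margin, length.out = n_ctrl) +
        runif(n_ctrl, -3, 3)
      xs <- sort(pmin(pmax(xs, margin), w - margin))
      y0 <- runif(1, margin + 2, h - margin - 2)
      ys <- y0 + cumsum(c(0, runif(n_ctrl - 1L, -h / 6, h / 6)))
      ys <- pmin(pmax(ys, margin), h - margin)
      # dense smooth polyline, ~2 points per pixel of width
      sx <- seq(min(xs), max(xs), length.out = 2L * w)
      sy <- stats::spline(xs, ys, xout = sx)$y
      sy <- pmin(pmax(sy, margin), h - margin)
      skeleton[[b]] <- cbind(y = sy, x = sx)
      radii[b] <- runif(1, 1.5, 3)
    }
    structure(list(class_id = as.integer(class_id), skeleton = skeleton,
                   vessel_radii = radii, canvas_size = c(h, w)),
              class = "finger_template")
  })
}

#' Session acquisition parameters
#'
#' Perturbations shared by every sample captured in one session: in-plane
#' rotation, translation, global brightness offset and optical blur. The
#' per-sample noise level is also declared here but realized independently
#' per sample. `session_seed` drives the (session-stable) background
#' illumination texture.
#'
#' @param rotation_deg rotation in degrees, |rotation| <= 10.
#' @param translation_px `c(dy, dx)` in pixels.
#' @param brightness_offset additive gray-level offset.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param noise_sigma per-sample Gaussian noise sigma in gray levels.
#' @param session_seed integer seed for the background texture.
#' @return object of class `session_params`.
#' @export
session_params <- function(rotation_deg = 0, translation_px = c(0, 0),
                           brightness_offset = 0, blur_sigma = 0,
                           noise_sigma = 0, session_seed = 0L) {
  if (abs(rotation_deg) > 10)
    stopf("|rotation_deg| must be <= 10; got %s", rotation_deg)
  structure(list(rotation_deg = rotation_deg,
                 translation_px = as.numeric(translation_px),
                 brightness_offset = brightness_offset,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 session_seed = as.integer(session_seed)),
            class = "session_params")
}

# Stamp discs of radius r around each polyline point; returns logical mask.
rasterize_skeleton <- function(skeleton, radii, h, w) {
  mask <- matrix(FALSE, h, w)
  for (b in seq_along(skeleton)) {
    r <- radii[b]
    ri <- ceiling(r)
    off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
    off <- off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
    pts <- skeleton[[b]]
    py <- round(pts[, 1L]); px <- round(pts[, 2L])
    keep <- !duplicated(cbind(py, px))
    py <- py[keep]; px <- px[keep]
    for (k in seq_along(off$dy)) {
      yy <- py + off$dy[k]; xx <- px + off$dx[k]
      ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
      mask[cbind(yy[ok], xx[ok])] <- TRUE
    }
  }
  mask
}

# Smooth background: horizontal illumination gradient plus a low-frequency
# texture, regenerated deterministically from the session seed.
render_background <- function(h, w, session_seed) {
  with_seed(derive_seed(session_seed, 777L), {
    base <- 175
    dir <- sample(c(-1, 1), 1L)
    grad <- matrix(rep(dir * seq(-12, 12, length.out = w), each = h), h, w)
    coarse <- matrix(runif(4 * 8, -12, 12), 4, 8)
    tex <- coarse[ceiling(seq_len(h) / (h / 4)),
                  ceiling(seq_len(w) / (w / 8)), drop = FALSE]
    tex <- gaussian_blur(tex, min(h, w) / 8)
    base + grad + tex
  })
}

#' Render one synthetic vein sample
#'
#' Applies the session transform (rotation about the canvas center, then
#' translation) to the template skeleton, rasterizes it into a vessel mask
#' dilated to the per-branch radii, and composes an 8-bit image: smooth
#' background minus a vein absorption term, plus session brightness, session
#' blur and per-sample Gaussian noise. Vein pixels are strictly darker than
#' background on average.
#'
#' @param template a [generate_template()] result.
#' @param session a [session_params()] object.
#' @param sample_seed integer seed for the noise realization.
#' @return list with `image` (numeric matrix, integers 0..255) and `mask`
#'   (binary 0/1 matrix).
#' @export
render_sample <- function(template, session = session_params(),
                          sample_seed = 0L) {
  stopifnot(inherits(template, "finger_template"),
            inherits(session, "session_params"))
  h <- template$canvas_size[1]; w <- template$canvas_size[2]
  th <- session$rotation_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  skel <- lapply(template$skeleton, function(p) {
    y <- p[, 1L] - cy; x <- p[, 2L] - cx
    cbind(y = cos(th) * y - sin(th) * x + cy + session$translation_px[1],
          x = sin(th) * y + cos(th) * x + cx + session$translation_px[2])
  })
  mask <- rasterize_skeleton(skel, template$vessel_radii, h, w)
  depth <- gaussian_blur(mask * 70, 0.8)
  img <- render_background(h, w, session$session_seed) - depth +
    session$brightness_offset
  if (session$blur_sigma > 0) img <- gaussian_blur(img, session$blur_sigma)
  if (session$noise_sigma > 0)
    img <- img + with_seed(sample_seed,
                           matrix(stats::rnorm(h * w, 0, session$noise_sigma),
                                  h, w))
  list(image = round(clamp255(img)), mask = mask * 1)
}

# Session parameter draws: session 1 is the (near-canonical) enrollment
# visit, later sessions carry larger placement and illumination drift.
draw_session_params <- function(class_id, session, master_seed) {
  sseed <- derive_seed(master_seed, class_id * 131L + session)
  with_seed(sseed, {
    if (session == 1L)
      session_params(rotation_deg = runif(1, -1, 1),
                     translation_px = round(runif(2, -1, 1)),
                     brightness_offset = 0, blur_sigma = 0.5,
                     noise_sigma = 3, session_seed = sseed)
    else
      session_params(rotation_deg = runif(1, -5, 5),
                     translation_px = round(runif(2, -3, 3)),
                     brightness_offset = runif(1, -12, 12),
                     blur_sigma = runif(1, 0.5, 1.0),
                     noise_sigma = 4, session_seed = sseed)
  })
}

#' Generate a complete synthetic SSPP dataset
#'
#' Builds `n_classes` finger templates and renders
#' `sessions * samples_per_session` images per class. When `out_dir` is
#' given, images and masks are written as 8-bit grayscale PNG under
#' `class_XXXX/session_Y/sample_Z.png` together with a `manifest.csv`
#' (columns `class_id,session,sample,path,mask_path,seed`). The SSPP split
#' is: train = session 1 sample 1, test = every sample of sessions >= 2.
#'
#' @param n_classes number of finger identities (>= 2).
#' @param sessions number of acquisition sessions (default 2).
#' @param samples_per_session samples per class per session.
#' @param master_seed integer master seed; full determinism in this value.
#' @param out_dir optional output directory.
#' @param canvas_size image size `c(h, w)`.
#' @return object of class `vein_dataset`: list with `samples` (each a list
#'   `image`, `mask`, `class_id`, `session`, `sample`, `seed`), `manifest`
#'   data frame, `n_classes`, `canvas_size`.
#' @export
generate_dataset <- function(n_classes, sessions = 2L,
                             samples_per_session = 6L, master_seed = 0L,
                             out_dir = NULL, canvas_size = c(64L, 128L)) {
  if (n_classes < 2) stopf("n_classes must be >= 2; got %s", n_classes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
      stopf("output directory '%s' is not writable", out_dir)
  }
  samples <- list()
  rows <- list()
  for (cls in seq_len(n_classes) - 1L) {
    tpl <- generate_template(cls, master_seed, canvas_size)
    for (ses in seq_len(sessions)) {
      sp <- draw_session_params(cls, ses, master_seed)
      for (smp in seq_len(samples_per_session)) {
        sseed <- derive_seed(master_seed, cls * 10000L + ses * 100L + smp)
        rend <- render_sample(tpl, sp, sseed)
        path <- mask_path <- NA_character_
        if (!is.null(out_dir)) {
          d <- file.path(out_dir, sprintf("class_%04d", cls),
                         sprintf("session_%d", ses))
          dir.create(d, recursive = TRUE, showWarnings = FALSE)
          path <- file.path(d, sprintf("sample_%d.png", smp))
          mask_path <- file.path(d, sprintf("sample_%d_mask.png", smp))
          write_gray_png(rend$image, path)
          write_gray_png(rend$mask * 255, mask_path)
        }
        samples[[length(samples) + 1L]] <-
          list(image = rend$image, mask = rend$mask, class_id = cls,
               session = ses, sample = smp, seed = sseed)
        rows[[length(rows) + 1L]] <-
          data.frame(class_id = cls, session = ses, sample = smp,
                     path = path, mask_path = mask_path, seed = sseed,
                     stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  structure(list(samples = samples, manifest = manifest,
                 n_classes = as.integer(n_classes),
                 canvas_size = as.integer(canvas_size)),
            class = "vein_dataset")
}

#' Split a dataset under the SSPP protocol
#'
#' Training set: the first sample of session 1 for every class (one image
#' per identity). Test set: all samples from sessions >= 2.
#'
#' @param dataset a `vein_dataset`.
#' @return list with `train` and `test`, both `vein_dataset` objects.
#' @export
sspp_split <- function(dataset) {
  stopifnot(inherits(dataset, "vein_dataset"))
  fm <- attr(dataset, "feature_maps")
  pick <- function(keep) {
    out <- structure(list(samples = dataset$samples[keep],
                          manifest = dataset$manifest[keep, , drop = FALSE],
                          n_classes = dataset$n_classes,
                          canvas_size = dataset$canvas_size),
                     class = "vein_dataset")
    if (!is.null(fm)) attr(out, "feature_maps") <- fm[keep]
    out
  }
  ses <- vapply(dataset$samples, `[[`, 0, "session")
  smp <- vapply(dataset$samples, `[[`, 0, "sample")
  list(train = pick(ses == 1 & smp == 1), test = pick(ses >= 2))
}

#' @export
print.vein_dataset <- function(x, ...) {
  cat(sprintf("<vein_dataset> %d samples, %d classes, canvas %dx%d\n",
              length(x$samples), x$n_classes,
              x$canvas_size[1], x$canvas_size[2]))
  invisible(x)
}
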