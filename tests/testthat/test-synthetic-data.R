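test_that("templates are deterministic, class-distinct and validated", {
  expect_identical(generate_template(0, 7), generate_template(0, 7))
  expect_error(generate_template(0, 7, c(16, 16)), "at least \\(32, 64\\)")

  t0 <- generate_template(0, 7)
  t1 <- generate_template(1, 7)
  m0 <- veinsemble:::rasterize_skeleton(t0$skeleton, t0$vessel_radii, 64, 128)
  m1 <- veinsemble:::rasterize_skeleton(t1$skeleton, t1$vessel_radii, 64, 128)
  expect_gt(sum(m0 != m1), 0)

  for (cl in 0:3) {
    tpl <- generate_template(cl, 3)
    expect_gte(length(tpl$skeleton), 3)
    for (b in tpl$skeleton) {
      expect_true(all(b[, "y"] >= 1 & b[, "y"] <= 64))
      expect_true(all(b[, "x"] >= 1 & b[, "x"] <= 128))
    }
  }
})

test_that("rendering honors vein darkness polarity and session semantics", {
  tpl <- generate_template(0, 7)

  # identity session: fully deterministic, mask equals the template mask
  clean <- render_sample(tpl, session_params(), 0)
  expect_identical(clean, render_sample(tpl, session_params(), 99))
  ref_mask <- veinsemble:::rasterize_skeleton(tpl$skeleton,
                                              tpl$vessel_radii, 64, 128)
  expect_identical(clean$mask, ref_mask * 1)

  # polarity holds across perturbed sessions and seeds
  for (seed in 1:3) {
    ses <- veinsemble:::draw_session_params(0, 2, seed)
    r <- render_sample(tpl, ses, seed)
    expect_lt(mean(r$image[r$mask == 1]), mean(r$image[r$mask == 0]))
    expect_true(all(r$image >= 0 & r$image <= 255))
    expect_true(all(r$image == round(r$image)))
  }

  # same session, two sample seeds: identical masks, images differ only by
  # the noise realization
  ses <- session_params(rotation_deg = 2, translation_px = c(1, -1),
                        brightness_offset = 5, blur_sigma = 0.6,
                        noise_sigma = 4, session_seed = 5)
  r1 <- render_sample(tpl, ses, 1)
  r2 <- render_sample(tpl, ses, 2)
  expect_identical(r1$mask, r2$mask)
  expect_gt(sum(r1$image != r2$image), 0)
  noise_free <- render_sample(tpl, session_params(
    rotation_deg = 2, translation_px = c(1, -1), brightness_offset = 5,
    blur_sigma = 0.6, noise_sigma = 0, session_seed = 5), 1)
  expect_lt(max(abs(r1$image - noise_free$image)), 4 * 6)  # noise bounded

  expect_error(session_params(rotation_deg = 30), "rotation")
})

test_that("generate_dataset counts, split and manifest determinism", {
  d1 <- file.path(tempdir(), "vs-gen-a")
  d2 <- file.path(tempdir(), "vs-gen-b")
  unlink(c(d1, d2), recursive = TRUE)
  ds <- generate_dataset(5, sessions = 2, samples_per_session = 3,
                         master_seed = 0, out_dir = d1)
  expect_length(ds$samples, 5 * 2 * 3)
  expect_equal(nrow(ds$manifest), 30)
  expect_true(all(file.exists(ds$manifest$path)))
  expect_true(all(file.exists(ds$manifest$mask_path)))

  split <- sspp_split(ds)
  expect_length(split$train$samples, 5)
  expect_length(split$test$samples, 5 * 3)
  expect_true(all(vapply(split$train$samples, `[[`, 0, "session") == 1))
  expect_true(all(vapply(split$test$samples, `[[`, 0, "session") == 2))

  generate_dataset(5, sessions = 2, samples_per_session = 3,
                   master_seed = 0, out_dir = d2)
  m1 <- readBin(file.path(d1, "manifest.csv"), "raw", 1e6)
  m2 <- readBin(file.path(d2, "manifest.csv"), "raw", 1e6)
  # manifests byte-identical up to the differing directory prefix
  expect_identical(rawToChar(m1),
                   gsub(basename(d2), basename(d1), rawToChar(m2),
                        fixed = TRUE))
  img1 <- readBin(ds$manifest$path[1], "raw", 1e6)
  img2 <- readBin(file.path(d2, "class_0000", "session_1", "sample_1.png"),
                  "raw", 1e6)
  expect_identical(img1, img2)

  expect_error(generate_dataset(1), "n_classes")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("FSIM nearest-neighbor identification beats chance on 10 classes", {
  ds <- generate_dataset(10, sessions = 2, samples_per_session = 1,
                         master_seed = 31)
  split <- sspp_split(ds)
  train_imgs <- lapply(split$train$samples, `[[`, "image")
  probe_imgs <- lapply(split$test$samples, `[[`, "image")
  train_pc <- lapply(train_imgs, phase_congruency)
  hits <- 0
  for (p in seq_along(probe_imgs)) {
    pcp <- phase_congruency(probe_imgs[[p]])
    sims <- vapply(seq_along(train_imgs), function(t)
      fsim(probe_imgs[[p]], train_imgs[[t]], pc1 = pcp,
           pc2 = train_pc[[t]]), 0)
    pred <- split$train$samples[[which.max(sims)]]$class_id
    hits <- hits + (pred == split$test$samples[[p]]$class_id)
  }
  expect_gt(hits / length(probe_imgs), 1 / 10)  # > chance
})

test_that("generated data carries class signal (masks are stable in class)", {
  s <- fx_samples()
  # same class, different sessions: masks overlap substantially after the
  # small session transforms; different classes overlap much less
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  d_intra <- dice(s$a1$mask == 1, s$a2$mask == 1)
  d_inter <- dice(s$a1$mask == 1, s$b1$mask == 1)
  expect_gt(d_intra, d_inter)
})
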