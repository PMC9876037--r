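# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A couple of rendered samples: same class two sessions, plus another class.
fx_samples <- function() {
  fixture("samples", {
    t0 <- generate_template(0, 42)
    t1 <- generate_template(1, 42)
    list(
      a1 = render_sample(t0, veinsemble:::draw_session_params(0, 1, 42), 1),
      a2 = render_sample(t0, veinsemble:::draw_session_params(0, 2, 42), 2),
      b1 = render_sample(t1, veinsemble:::draw_session_params(1, 1, 42), 3))
  })
}

# Tiny on-disk dataset reused by the cli_io tests.
fx_disk_dataset <- function() {
  fixture("disk_ds", {
    dir <- file.path(tempdir(), "veinsemble-fixture-ds")
    unlink(dir, recursive = TRUE)
    ds <- generate_dataset(4, sessions = 2, samples_per_session = 2,
                           master_seed = 7, out_dir = dir)
    list(dir = dir, ds = ds)
  })
}

# Small in-memory dataset with feature maps, for ensemble tests.
fx_small_dataset <- function() {
  fixture("small_ds", {
    precompute_feature_maps(
      generate_dataset(4, sessions = 2, samples_per_session = 1,
                       master_seed = 11))
  })
}
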