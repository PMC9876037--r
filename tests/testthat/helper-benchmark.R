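# Seeded SSPP benchmark shared by the acceptance criteria.
#
# The stated benchmark (30 classes, 6 samples/session, seeds 0-4, the
# package's K = 50 x P = 4 default schedule) needs hours of single-CPU
# time; the suite runs a documented scale-down: 10 classes, 2 sessions,
# 3 samples/session, 64x128 images with 64x64 CNN inputs, K = 5 steps of
# P = 8 epochs, seeds 0-2. P = 8 is the smallest P for which the
# shared-epoch rule 2*floor(P/4 * St) - 1 can fire for St < 1, so the
# three regimes stay genuinely distinct; K is the largest step count that
# fits the CPU budget. See the methods vignette.

bench_config <- function(seed) {
  ensemble_config(K_steps = 5, P_epochs = 8, seed = seed,
                  input_shape = c(64, 64))
}

bench_results <- function() {
  fixture("bench", {
    out <- list()
    for (seed in 0:2) {
      ds <- generate_dataset(10, sessions = 2, samples_per_session = 3,
                             master_seed = seed)
      ds <- precompute_feature_maps(ds)
      split <- sspp_split(ds)
      runs <- list()
      for (reg in c("basic", "shared", "full")) {
        m <- suppressWarnings(
          veinsemble:::train_ensemble(ds, bench_config(seed), reg))
        ev <- evaluate(m, split$test)
        runs[[reg]] <- list(accuracy = ev$accuracy,
                            per_classifier = ev$per_classifier,
                            history = m$history, w = m$w,
                            fallback = m$fallback)
      }
      out[[as.character(seed)]] <- runs
    }
    out
  })
}
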