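# Shared fixtures, built once per test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small rendered cohort with trained frame models: 15 annotated training
# videos, 10 held-out, default generator conditions.
small_cohort <- function() {
  fixture("small_cohort", {
    spec <- generator_spec(n_videos = 25, seed = 7)
    ds <- simulate_dataset(spec)
    feats <- list()
    truth <- list()
    for (i in 1:15) {
      rv <- render_embryo(ds, i)
      f <- frame_features(rv$video)
      keep <- seq(1, nrow(f), by = 3)
      feats[[i]] <- f[keep, , drop = FALSE]
      truth[[i]] <- rv$truth[keep, , drop = FALSE]
    }
    train_feats <- do.call(rbind, feats)
    train_truth <- do.call(rbind, truth)
    models <- train_prep_models(train_feats, train_truth)
    heldout <- lapply(16:25, function(i) {
      rv <- render_embryo(ds, i)
      list(video = rv$video, truth = rv$truth, features = frame_features(rv$video),
           schedule = ds$videos[[i]]$schedule)
    })
    list(spec = spec, ds = ds, models = models, heldout = heldout,
         train_feats = train_feats, train_truth = train_truth)
  })
}

# Temporal windows with labels deterministic in the 2->3-cell interval,
# built from ground-truth tags (no rendering).
deterministic_windows <- function(n = 500, seed = 99) {
  fixture(paste0("det_windows_", n, "_", seed), {
    spec <- generator_spec(seed = seed)
    set.seed(seed)
    wins <- vector("list", n)
    y <- integer(n)
    for (i in seq_len(n)) {
      s <- sample_schedule(spec)
      gt <- ground_truth(s, frame_count = 800)
      wins[[i]] <- extract_temporal_window(gt, min(s$pnf_frame, 300))
      i23 <- s$division_frames[2] - s$division_frames[1]
      y[i] <- as.integer(i23 <= spec$cleavage_interval_means[2])
    }
    list(windows = wins, labels = y)
  })
}

# Full-scale prepared dataset for the end-to-end checks (default generator
# conditions, n = 500 embryos).
endtoend_prepared <- function() {
  fixture("endtoend_prepared", {
    spec <- generator_spec(n_videos = 500, seed = 20)
    ds <- simulate_dataset(spec)
    prepare_analysis(ds, pipeline_config(), seed = 1)
  })
}
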