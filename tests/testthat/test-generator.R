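test_that("PNF timing honours the method-specific means when sd is zero", {
  spec <- generator_spec(pnf_sd = 0, seed = 1)
  set.seed(1)
  expect_equal(sample_schedule(spec, method = "IVF")$pnf_frame, 235L)
  expect_equal(sample_schedule(spec, method = "ICSI")$pnf_frame, 271L)
})

test_that("schedules are deterministic given the RNG state and well ordered", {
  spec <- generator_spec(seed = 3)
  set.seed(11)
  a <- sample_schedule(spec)
  set.seed(11)
  b <- sample_schedule(spec)
  expect_identical(a, b)
  for (i in 1:50) {
    s <- sample_schedule(spec)
    expect_true(all(diff(s$division_frames) > 0))
    expect_lte(s$pnf_frame, s$division_frames[1])
    expect_lt(s$pn_appear_frame, s$pnf_frame)
    expect_gte(s$morphology_score, 0)
    expect_lte(s$morphology_score, 1)
    expect_true(s$pnf_frame >= 150 && s$pnf_frame <= 350)
  }
})

test_that("the threshold outcome rule behaves as constructed", {
  spec <- generator_spec(seed = 1)
  make_sched <- function(intervals, morph) {
    structure(list(method = "IVF", frame_count = 780L, pn_appear_frame = 50L,
                   pnf_frame = 235L,
                   division_frames = as.integer(235 + cumsum(intervals)),
                   morphology_score = morph),
              class = "cleavage_schedule")
  }
  m <- spec$cleavage_interval_means
  # on-time cleaver with pristine morphology
  expect_equal(assign_outcome(make_sched(m, 1.0), spec),
               c(blastocyst = 1L, usable = 1L))
  # severely delayed first cleavage interval
  delayed <- m
  delayed[1] <- 3 * m[1]
  expect_equal(assign_outcome(make_sched(delayed, 1.0), spec),
               c(blastocyst = 0L, usable = 0L))
  # blastocyst but fragmented -> not usable
  expect_equal(assign_outcome(make_sched(m, 0.1), spec),
               c(blastocyst = 1L, usable = 0L))
  bad_spec <- spec
  bad_spec$outcome_rule <- "mystery"
  expect_error(assign_outcome(make_sched(m, 1), bad_spec), "outcome_rule")
})

test_that("label structure and prevalence hold over a large simulated cohort", {
  spec <- generator_spec(n_videos = 1000, seed = 5)
  ds <- simulate_dataset(spec)
  labs <- t(vapply(ds$videos, function(v) v$labels, integer(2)))
  # usable implies blastocyst, without exception
  expect_equal(sum(labs[, "usable"] > labs[, "blastocyst"]), 0)
  # prevalence within 5 percentage points of the configured target
  expect_lt(abs(mean(labs[, "blastocyst"]) - spec$blast_rate), 0.05)
})

test_that("the 3-cell stage occupies the smallest frame share", {
  spec <- generator_spec(n_videos = 200, seed = 5)
  ds <- simulate_dataset(spec)
  shares <- rowMeans(vapply(ds$videos, function(v) {
    gt <- ground_truth(v$schedule)
    tabulate(gt$stage, 5) / nrow(gt)
  }, numeric(5)))
  expect_equal(which.min(shares), 3L)
})

test_that("rendered stacks agree with their ground truth", {
  spec <- generator_spec(n_videos = 1, stage_noise_rate = 0, seed = 21)
  ds <- simulate_dataset(spec)
  rv <- render_embryo(ds, 1)
  s <- ds$videos[[1]]$schedule
  expect_equal(dim(rv$video$frames)[3], s$frame_count)
  expect_equal(nrow(rv$truth), s$frame_count)
  # no PN before its appearance or after fading
  expect_true(all(rv$truth$pn[rv$truth$frame < s$pn_appear_frame] == 0))
  expect_true(all(rv$truth$pn[rv$truth$frame > s$pnf_frame] == 0))
})

test_that("PN discs outshine the surrounding cytoplasm on clean frames", {
  spec <- generator_spec(n_videos = 1, stage_noise_rate = 0, seed = 22)
  ds <- simulate_dataset(spec)
  rv <- render_embryo(ds, 1)
  s <- ds$videos[[1]]$schedule
  size <- spec$image_size
  c0 <- (size - 1) / 2
  xy <- expand.grid(x = 0:(size - 1), y = 0:(size - 1))
  pn_mask <- rep(FALSE, nrow(xy))
  for (dx in c(-0.055, 0.055)) {
    pn_mask <- pn_mask | (sqrt((xy$x - (c0 + dx * size))^2 +
                                 (xy$y - c0)^2) <= 0.045 * size)
  }
  cyto_mask <- sqrt((xy$x - c0)^2 + (xy$y - c0)^2) <= 0.28 * size & !pn_mask
  pn_frames <- which(rv$truth$pn == 1)
  pn_frames <- pn_frames[seq(1, length(pn_frames), length.out = 100)]
  ok <- vapply(pn_frames, function(f) {
    img <- rv$video$frames[, , f]
    mean(img[pn_mask]) > mean(img[cyto_mask])
  }, logical(1))
  expect_equal(sum(ok), 100L)
})

test_that("datasets round-trip through disk and are hash-stable", {
  spec <- generator_spec(n_videos = 10, frame_count_range = c(60, 80),
                         pn_appear_range = c(5, 10), seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_dataset(spec, d1)
  m2 <- write_dataset(spec, d2)
  expect_equal(nrow(m1), 10)
  expect_identical(m1, m2)
  # identical spec + seed -> byte-identical video files
  expect_identical(unname(tools::md5sum(file.path(d1, m1$file))),
                   unname(tools::md5sum(file.path(d2, m2$file))))
  back <- read_manifest(d1)
  expect_equal(back$blastocyst, m1$blastocyst)
  expect_equal(back$usable, m1$usable)
  expect_equal(back$pnf_frame, m1$pnf_frame)
  emb <- read_embryo(d1, back[1, ])
  expect_equal(dim(emb$video$frames)[3], back$frame_count[1])
  expect_equal(emb$truth$stage,
               ground_truth(simulate_dataset(spec)$videos[[1]]$schedule)$stage)
})

test_that("degenerate generator parameters are rejected", {
  expect_error(generator_spec(image_size = 16))
  expect_error(generator_spec(fertilization_mix = 1.5))
  expect_error(generator_spec(cleavage_interval_means = c(-1, 10, 10, 10)))
})
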