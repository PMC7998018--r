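test_that("1-cell recognition tracks the ground-truth mask on held-out videos", {
  cohort <- small_cohort()
  agree <- vapply(cohort$heldout, function(h) {
    seq <- classify_one_cell(h$features, cohort$models$one_cell)
    expect_length(seq, nrow(h$features))
    mean(seq == as.integer(h$truth$stage == 1))
  }, numeric(1))
  expect_gte(mean(agree), 0.99)
})

test_that("a constant blank video is assigned a single class", {
  cohort <- small_cohort()
  blank <- embryo_video(array(0.5, dim = c(64, 64, 20)))
  seq <- classify_one_cell(blank, cohort$models$one_cell)
  expect_length(unique(seq), 1)
})

test_that("PN estimation is masked by the 1-cell stage and accurate", {
  cohort <- small_cohort()
  agree <- vapply(cohort$heldout, function(h) {
    one_cell <- classify_one_cell(h$features, cohort$models$one_cell)
    pn <- detect_pn(h$features, one_cell, cohort$models$pn)
    expect_length(pn, nrow(h$features))
    # frames after the first division carry no PN call
    after <- h$truth$frame > h$schedule$division_frames[1]
    expect_true(all(pn[after & one_cell == 0] == 0))
    mean(pn == h$truth$pn)
  }, numeric(1))
  expect_gte(mean(agree), 0.90)
  expect_error(
    detect_pn(cohort$heldout[[1]]$features, c(0L, 1L), cohort$models$pn),
    "length")
})

test_that("PNF is the last 1 of the corrected sequence", {
  expect_equal(locate_pnf(c(1, 1, 1, 0, 0)), list(frame = 2L, found = TRUE))
  expect_false(locate_pnf(c(0, 0, 0))$found)
  expect_equal(locate_pnf(c(rep(1L, 300), rep(0L, 200)))$frame, 299L)
})

test_that("PNF correctness uses the 10-frame tolerance", {
  est <- function(f) list(frame = f, found = TRUE)
  expect_true(pnf_is_correct(est(240), 235))
  expect_false(pnf_is_correct(est(250), 235))
  expect_true(pnf_is_correct(est(245), 235))
  expect_false(pnf_is_correct(list(frame = NA, found = FALSE), 235))
})

test_that("screening enforces video length and window feasibility", {
  est <- function(f) list(frame = f, found = TRUE)
  expect_true(screen_video(800L, est(235))$retain)
  expect_equal(screen_video(700L, est(235))$reason, "too_short")
  expect_equal(screen_video(760L, est(270))$reason, "window_out_of_range")
  expect_equal(screen_video(800L, est(99))$reason, "window_out_of_range")
  expect_equal(screen_video(800L, list(frame = NA, found = FALSE))$reason,
               "pnf_not_found")
  # a retained video supports the temporal window and all 35 checkpoints
  ok <- screen_video(800L, est(235))
  expect_true(ok$retain)
  idx <- checkpoint_indices(235)
  expect_true(all(idx >= 235 - 100 & idx <= 235 + 499))
})

test_that("PNF recovery on held-out synthetic videos is within tolerance", {
  cohort <- small_cohort()
  ok <- vapply(cohort$heldout, function(h) {
    prep <- prepare_video(h$video, cohort$models, features = h$features)
    pnf_is_correct(prep$pnf, h$schedule$pnf_frame)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
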