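# Video preparation: 1-cell recognition, PN presence estimation, the
# run-length correction filter, PNF localization and video screening.
#
# PNF (pronuclear fading) is the alignment origin of the whole pipeline: the
# temporal window and the five spatial checkpoints are all expressed as frame
# offsets from it, which removes the systematic timing difference between IVF
# and ICSI embryos.

#' Classify each frame as 1-cell or multicell
#'
#' @param video an [embryo_video()] (or a precomputed descriptor matrix).
#' @param model a binary [fit_frame_classifier()] trained with levels
#'   `c("0", "1")` where `"1"` means 1-cell stage (see
#'   [train_prep_models()]).
#' @return integer 0/1 vector, one value per frame; 1 = 1-cell stage.
#' @export
classify_one_cell <- function(video, model) {
  feats <- if (is.matrix(video)) video else frame_features(video)
  as.integer(as.character(predict(model, feats)))
}

#' Estimate pronuclei presence per frame
#'
#' Applies the PN classifier to the frames flagged as 1-cell stage; frames
#' outside the 1-cell stage are assigned 0 (the pronuclei can only be seen
#' before the first cleavage), keeping the output aligned with the frames.
#'
#' @param video an [embryo_video()] (or a precomputed descriptor matrix).
#' @param one_cell 0/1 vector from [classify_one_cell()], same length as the
#'   video.
#' @param model a binary [fit_frame_classifier()] for PN presence (levels
#'   `c("0", "1")`, `"1"` = pronuclei visible).
#' @return integer 0/1 vector, one value per frame; 1 = pronuclei present.
#' @export
detect_pn <- function(video, one_cell, model) {
  feats <- if (is.matrix(video)) video else frame_features(video)
  if (length(one_cell) != nrow(feats)) {
    stop("one_cell sequence length does not match the frame count")
  }
  out <- integer(nrow(feats))
  idx <- which(one_cell == 1L)
  if (length(idx) > 0) {
    out[idx] <- as.integer(as.character(predict(model, feats[idx, ,
                                                             drop = FALSE])))
  }
  out
}

# Run-length decomposition helpers for the correction filter.
flip_run <- function(seq, runs, j) {
  start <- if (j == 1) 1L else sum(runs$lengths[1:(j - 1)]) + 1L
  end <- start + runs$lengths[j] - 1L
  seq[start:end] <- 1L - seq[start:end]
  seq
}

# One full i = 1..k sweep; within each i, flips are applied leftmost-first
# with immediate effect (the run decomposition is rebuilt after every flip).
correction_sweep <- function(seq, k) {
  for (i in seq_len(k)) {
    repeat {
      runs <- rle(seq)
      nr <- length(runs$lengths)
      if (nr < 3) break
      flipped <- FALSE
      for (j in 2:(nr - 1)) {
        num <- runs$lengths[j]
        if (num != i) next
        jl <- runs$lengths[j - 1]
        jr <- runs$lengths[j + 1]
        if ((jl >= i && jr >= i + 1) || (jr >= i && jl >= i + 1)) {
          seq <- flip_run(seq, runs, j)
          flipped <- TRUE
          break
        }
      }
      if (!flipped) break
    }
  }
  seq
}

#' Correction filter for noisy binary per-frame sequences
#'
#' Suppresses noisy segments in classifier output sequences: a run of
#' identical values that disagrees with its flanking runs is flipped when it
#' is short relative to them. For `i = 1, ..., k` in order, every interior
#' run of length exactly `i` whose flanking run lengths `j_left`, `j_right`
#' satisfy `(j_left >= i and j_right >= i + 1)` or
#' `(j_right >= i and j_left >= i + 1)` is flipped to the flanking value;
#' each `i` starts from the previous `i`'s result, and the whole `k`-pass is
#' repeated until a fixed point. Runs touching either end of the sequence
#' have only one neighbour and are never corrected.
#'
#' @param seq integer 0/1 vector.
#' @param k maximum noisy-segment length considered (default 6).
#' @param max_sweeps safety cap on the outer fixed-point iteration.
#' @return the corrected 0/1 vector, same length.
#' @export
correct_sequence <- function(seq, k = 6L, max_sweeps = 50L) {
  if (length(seq) == 0) stop("empty sequence")
  if (!all(seq %in% c(0L, 1L))) stop("sequence must be binary 0/1")
  seq <- as.integer(seq)
  for (s in seq_len(max_sweeps)) {
    out <- correction_sweep(seq, k)
    if (identical(out, seq)) return(out)
    seq <- out
  }
  stop("correction filter did not reach a fixed point within ", max_sweeps,
       " sweeps")
}

#' Locate the pronuclear-fading frame
#'
#' PNF is the last frame at which the pronuclei are present, i.e. the index
#' of the last 1 in the (corrected) PN presence sequence.
#'
#' @param seq 0/1 PN presence sequence.
#' @return list with `frame` (0-based index of the last 1, or `NA`) and
#'   `found` (logical).
#' @export
locate_pnf <- function(seq) {
  ones <- which(seq == 1L)
  if (length(ones) == 0) {
    list(frame = NA_integer_, found = FALSE)
  } else {
    list(frame = max(ones) - 1L, found = TRUE)
  }
}

#' Is a PNF estimate correct?
#'
#' As the pronuclei fade gradually, an estimate is considered correct when it
#' deviates from the labeled frame by at most `tol` frames.
#'
#' @param estimate a [locate_pnf()] result.
#' @param labeled true PNF frame index.
#' @param tol tolerance in frames (default 10).
#' @return logical; `FALSE` when the estimate was not found.
#' @export
pnf_is_correct <- function(estimate, labeled, tol = 10) {
  if (!isTRUE(estimate$found)) return(FALSE)
  abs(estimate$frame - labeled) <= tol
}

#' Screen a video for the prediction models
#'
#' A video is retained when it is longer than 750 frames, its PNF was found,
#' and the PNF supports the full PNF-anchored analysis window: the temporal
#' window spans PNF-100 to PNF+499 (which also covers all 35 spatial
#' checkpoint frames), so `pnf >= 100` and `pnf + 499` must not exceed the
#' last frame index.
#'
#' @param video an [embryo_video()], or an integer frame count.
#' @param pnf a [locate_pnf()] result.
#' @return list with `retain` (logical) and `reason` (`"retained"`,
#'   `"too_short"`, `"pnf_not_found"` or `"window_out_of_range"`).
#' @export
screen_video <- function(video, pnf) {
  n <- if (inherits(video, "embryo_video")) n_frames(video) else
    as.integer(video)
  if (n <= 750L) {
    return(list(retain = FALSE, reason = "too_short"))
  }
  if (!isTRUE(pnf$found)) {
    return(list(retain = FALSE, reason = "pnf_not_found"))
  }
  if (pnf$frame < 100L || pnf$frame + 499L > n - 1L) {
    return(list(retain = FALSE, reason = "window_out_of_range"))
  }
  list(retain = TRUE, reason = "retained")
}

#' Train the video-preparation frame models on annotated videos
#'
#' Fits three descriptor-based classifiers: 1-cell vs multicell (all frames),
#' PN presence (trained on the true 1-cell-stage frames only) and the 5-way
#' cell stage.
#'
#' @param features descriptor matrix of the annotated frames.
#' @param truth data frame with `stage` (1..5) and `pn` (0/1) for those
#'   frames.
#' @param stage_config a [stage_classifier_config()] for the cell-stage
#'   model; the binary models use cross-entropy (gamma 0).
#' @return list of class `prep_models` with `one_cell`, `pn` and `stage`.
#' @export
train_prep_models <- function(features, truth,
                              stage_config = stage_classifier_config()) {
  stopifnot(nrow(features) == nrow(truth))
  one_cell_lab <- factor(as.integer(truth$stage == 1L), levels = 0:1)
  set.seed(stage_config$seed)
  one_cell <- fit_frame_classifier(features, one_cell_lab, gamma = 0,
                                   class_weights = NULL)
  idx1 <- which(truth$stage == 1L)
  if (length(unique(truth$pn[idx1])) < 2) {
    stop("PN training requires 1-cell frames with and without pronuclei")
  }
  pn <- fit_frame_classifier(features[idx1, , drop = FALSE],
                             factor(truth$pn[idx1], levels = 0:1),
                             gamma = 0, class_weights = NULL)
  stage <- train_stage_classifier(features, truth$stage, stage_config)
  structure(list(one_cell = one_cell, pn = pn, stage = stage),
            class = "prep_models")
}

#' Prepare one video: sequences, PNF and screening decision
#'
#' Runs the full preparation chain: 1-cell recognition, PN presence
#' estimation, the correction filter ([correct_sequence()]) on the PN
#' sequence, PNF localization and screening.
#'
#' @param video an [embryo_video()].
#' @param models a [train_prep_models()] result.
#' @param k correction-filter order.
#' @param features optional precomputed [frame_features()] matrix.
#' @return list with `one_cell`, `pn_raw`, `pn` (corrected), `pnf`
#'   ([locate_pnf()] result), `screen` ([screen_video()] result) and
#'   `features`.
#' @export
prepare_video <- function(video, models, k = 6L, features = NULL) {
  stopifnot(inherits(models, "prep_models"))
  if (is.null(features)) features <- frame_features(video)
  one_cell <- classify_one_cell(features, models$one_cell)
  pn_raw <- detect_pn(features, one_cell, models$pn)
  pn <- correct_sequence(pn_raw, k = k)
  pnf <- locate_pnf(pn)
  screen <- screen_video(nrow(features), pnf)
  list(one_cell = one_cell, pn_raw = pn_raw, pn = pn, pnf = pnf,
       screen = screen, features = features)
}
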