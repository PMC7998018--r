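# Synthetic time-lapse embryo-video generator.
#
# Emulates the statistical structure the prediction pipeline relies on:
# pronuclei (PN) that appear and then fade during the 1-cell stage, cleavage
# events through the 1/2/3/4/>=5-cell stages with the strongly imbalanced
# stage durations seen in clinical frame sets, occasional degraded frames,
# and outcome labels coupled to both cleavage timings (temporal signal) and
# a rendered morphology score (spatial signal).

#' Specification of a synthetic embryo-video dataset
#'
#' Collects every knob of the synthetic generator: cohort size, video length,
#' fertilization-method mix, the pronuclear-fading (PNF) timing distributions
#' for IVF and ICSI embryos, cleavage-interval means, rendering parameters and
#' the outcome-coupling rule. Defaults reproduce the clinically reported
#' regime: videos of 750-800 frames at one frame per 5 minutes, PNF centred on
#' frame 235 (IVF, range 150-300) or 271 (ICSI, range 200-350), and cleavage
#' intervals whose means give the characteristic frame shares of roughly
#' 42/16/6/18/18 percent for the 1/2/3/4/5+-cell stages (the 3-cell stage is
#' by far the rarest).
#'
#' @param n_videos number of embryos to simulate.
#' @param frame_count_range integer pair; video length is sampled uniformly
#'   from this inclusive range (frames, one per 5 minutes).
#' @param fertilization_mix fraction of embryos fertilized by ICSI (the rest
#'   are standard IVF).
#' @param pnf_mean_ivf,pnf_mean_icsi mean PNF frame for IVF / ICSI embryos.
#' @param pnf_sd standard deviation of the PNF frame; the distribution is a
#'   normal truncated to `pnf_range_ivf` / `pnf_range_icsi`.
#' @param pnf_range_ivf,pnf_range_icsi inclusive truncation ranges.
#' @param cleavage_interval_means mean frame intervals for the four stage
#'   transitions (PNF to 2-cell, 2- to 3-cell, 3- to 4-cell, 4- to 5+-cell).
#' @param interval_shape gamma shape parameter of the cleavage intervals
#'   (larger = more regular cleaver; shape 16 gives a 25% coefficient of
#'   variation).
#' @param pn_appear_range inclusive frame range in which the pronuclei first
#'   become visible.
#' @param stage_noise_rate probability that a frame's rendered appearance is
#'   degraded (washed out and noisy), emulating indecipherable or obscured
#'   frames.
#' @param outcome_rule name of the rule coupling schedules to labels; only
#'   `"threshold"` is defined (see [assign_outcome()]).
#' @param blast_rate target blastocyst prevalence under the threshold rule.
#' @param usable_frac target fraction of blastocysts that are usable.
#' @param label_noise probability of independently flipping each outcome
#'   label (the usable label is re-masked so usable implies blastocyst).
#' @param image_size side length of the square frames, pixels.
#' @param seed integer seed; a spec plus its seed fully determines the
#'   dataset.
#' @return an object of class `generator_spec`.
#' @seealso [sample_schedule()], [simulate_dataset()], [write_dataset()]
#' @export
generator_spec <- function(n_videos = 100,
                           frame_count_range = c(750L, 800L),
                           fertilization_mix = 0.5,
                           pnf_mean_ivf = 235,
                           pnf_mean_icsi = 271,
                           pnf_sd = 30,
                           pnf_range_ivf = c(150, 300),
                           pnf_range_icsi = c(200, 350),
                           cleavage_interval_means = c(90, 124, 46, 140),
                           interval_shape = 16,
                           pn_appear_range = c(30, 80),
                           stage_noise_rate = 0.02,
                           outcome_rule = "threshold",
                           blast_rate = 0.6,
                           usable_frac = 0.6,
                           label_noise = 0,
                           image_size = 64L,
                           seed = 1L) {
  stopifnot(
    n_videos >= 1,
    length(frame_count_range) == 2, frame_count_range[1] >= 1,
    frame_count_range[1] <= frame_count_range[2],
    fertilization_mix >= 0, fertilization_mix <= 1,
    pnf_mean_ivf > 0, pnf_mean_icsi > 0, pnf_sd >= 0,
    length(cleavage_interval_means) == 4, all(cleavage_interval_means > 0),
    interval_shape > 0,
    stage_noise_rate >= 0, stage_noise_rate <= 1,
    blast_rate > 0, blast_rate <= 1,
    usable_frac >= 0, usable_frac <= 1,
    label_noise >= 0, label_noise <= 1,
    image_size >= 32
  )
  spec <- list(
    n_videos = as.integer(n_videos),
    frame_count_range = as.integer(frame_count_range),
    fertilization_mix = fertilization_mix,
    pnf_mean_ivf = pnf_mean_ivf, pnf_mean_icsi = pnf_mean_icsi,
    pnf_sd = pnf_sd,
    pnf_range_ivf = pnf_range_ivf, pnf_range_icsi = pnf_range_icsi,
    cleavage_interval_means = cleavage_interval_means,
    interval_shape = interval_shape,
    pn_appear_range = pn_appear_range,
    stage_noise_rate = stage_noise_rate,
    outcome_rule = outcome_rule,
    blast_rate = blast_rate, usable_frac = usable_frac,
    label_noise = label_noise,
    image_size = as.integer(image_size),
    seed = as.integer(seed)
  )
  class(spec) <- "generator_spec"
  spec
}

# Thresholds of the default outcome rule. Each of the first three cleavage
# intervals must fall below the q-quantile of its sampling distribution with
# q = blast_rate^(1/3), so P(all three pass) equals the configured prevalence.
outcome_thresholds <- function(spec) {
  q <- spec$blast_rate^(1 / 3)
  m <- spec$cleavage_interval_means[1:3]
  list(
    interval = qgamma(q, shape = spec$interval_shape,
                      rate = spec$interval_shape / m),
    morphology = 1 - spec$usable_frac
  )
}

rtruncnorm1 <- function(mean, sd, range, max_tries = 1000L) {
  if (sd == 0) {
    return(min(max(mean, range[1]), range[2]))
  }
  for (i in seq_len(max_tries)) {
    x <- rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  stop("failed to sample a truncated normal after ", max_tries, " tries")
}

#' Sample a cleavage schedule for one synthetic embryo
#'
#' Draws the morphokinetic skeleton of a video: PN appearance frame, PNF frame
#' (truncated normal, method-specific), the four division frames (PNF plus
#' cumulative gamma-distributed intervals) and a morphology score in \[0, 1\]
#' (1 = pristine cytoplasm, 0 = heavily fragmented). Uses the current R
#' random-number state; seed the session (or use [simulate_dataset()]) for
#' reproducibility.
#'
#' @param spec a [generator_spec()].
#' @param method `"IVF"` or `"ICSI"`; if `NULL`, drawn from
#'   `spec$fertilization_mix`.
#' @return an object of class `cleavage_schedule` with fields `method`,
#'   `frame_count`, `pn_appear_frame`, `pnf_frame`, `division_frames` (the
#'   frames at which the 2-, 3-, 4- and 5+-cell stages begin) and
#'   `morphology_score`. Frame indices are 0-based.
#' @export
sample_schedule <- function(spec, method = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(method)) {
    method <- if (runif(1) < spec$fertilization_mix) "ICSI" else "IVF"
  }
  method <- match.arg(method, c("IVF", "ICSI"))
  frame_count <- spec$frame_count_range[1] +
    sample.int(spec$frame_count_range[2] - spec$frame_count_range[1] + 1L,
               1L) - 1L
  pnf <- if (method == "IVF") {
    rtruncnorm1(spec$pnf_mean_ivf, spec$pnf_sd, spec$pnf_range_ivf)
  } else {
    rtruncnorm1(spec$pnf_mean_icsi, spec$pnf_sd, spec$pnf_range_icsi)
  }
  pnf <- as.integer(round(pnf))
  intervals <- pmax(1, round(rgamma(
    4, shape = spec$interval_shape,
    rate = spec$interval_shape / spec$cleavage_interval_means
  )))
  pn_appear <- as.integer(round(runif(1, spec$pn_appear_range[1],
                                      spec$pn_appear_range[2])))
  pn_appear <- min(pn_appear, pnf - 1L)
  schedule <- list(
    method = method,
    frame_count = frame_count,
    pn_appear_frame = pn_appear,
    pnf_frame = pnf,
    division_frames = as.integer(pnf + cumsum(intervals)),
    morphology_score = runif(1)
  )
  class(schedule) <- "cleavage_schedule"
  schedule
}

#' Assign outcome labels to a cleavage schedule
#'
#' The default `"threshold"` rule encodes the premise that morphokinetics and
#' morphology carry complementary signal: the embryo forms a blastocyst iff
#' each of its first three cleavage intervals (PNF to 2-cell, 2- to 3-cell,
#' 3- to 4-cell) is below a fixed quantile threshold of its sampling
#' distribution, and a blastocyst is usable iff in addition its morphology
#' score clears `1 - usable_frac`. With `label_noise = 0` the labels are a
#' deterministic function of the schedule; label noise flips each label
#' independently and then re-imposes usable => blastocyst.
#'
#' @param schedule a [sample_schedule()] result.
#' @param spec the [generator_spec()] the schedule was drawn under.
#' @return named integer vector `c(blastocyst = 0/1, usable = 0/1)`.
#' @export
assign_outcome <- function(schedule, spec) {
  stopifnot(inherits(schedule, "cleavage_schedule"),
            inherits(spec, "generator_spec"))
  if (!identical(spec$outcome_rule, "threshold")) {
    stop("unknown outcome_rule: ", spec$outcome_rule)
  }
  thr <- outcome_thresholds(spec)
  intervals <- diff(c(schedule$pnf_frame, schedule$division_frames))[1:3]
  blast <- as.integer(all(intervals <= thr$interval))
  usable <- as.integer(blast == 1L &&
                         schedule$morphology_score >= thr$morphology)
  if (spec$label_noise > 0) {
    if (runif(1) < spec$label_noise) blast <- 1L - blast
    if (runif(1) < spec$label_noise) usable <- 1L - usable
    usable <- usable * blast
  }
  c(blastocyst = blast, usable = usable)
}

#' Per-frame ground truth for a schedule
#'
#' @param schedule a [sample_schedule()] result.
#' @param frame_count number of frames (defaults to the schedule's own).
#' @return data frame with 0-based `frame`, `stage` (1-5, where 5 denotes the
#'   open-ended 5+ class) and `pn` (0/1 pronuclei visible).
#' @export
ground_truth <- function(schedule, frame_count = schedule$frame_count) {
  frame <- seq_len(frame_count) - 1L
  stage <- 1L + findInterval(frame, schedule$division_frames)
  stage <- pmin(stage, 5L)
  pn <- as.integer(frame >= schedule$pn_appear_frame &
                     frame <= schedule$pnf_frame)
  data.frame(frame = frame, stage = stage, pn = pn)
}

# Blastomere layouts per stage: rows of (dx, dy, r) in units of image size,
# relative to the frame centre. Radii and placements keep >= ~2 px gaps
# between cells at a 64 px frame so the thresholded mask separates them.
cell_layouts <- function() {
  deg <- function(a) a * pi / 180
  ring <- function(n, d, r, offset = 90) {
    a <- deg(offset + (0:(n - 1)) * 360 / n)
    cbind(d * cos(a), d * sin(a), r)
  }
  list(
    cbind(0, 0, 0.28),
    cbind(c(-0.17, 0.17), 0, 0.15),
    ring(3, 0.16, 0.12),
    ring(4, 0.17, 0.105, offset = 45),
    rbind(ring(4, 0.20, 0.085, offset = 45), cbind(0, 0, 0.085))
  )
}

render_params <- function() {
  c(bg = 0.08, well_r = 0.47, well_val = 0.25, cyto = 0.55,
    speckle_r = 0.018, speckle_val = 0.42, pn_val = 0.92, noise_sd = 0.025,
    degrade_gain = 0.25, degrade_offset = 0.35, degrade_noise = 0.12)
}

pn_disc_layout <- function() {
  cbind(c(-0.055, 0.055), 0, 0.045)
}

#' Construct an embryo video object
#'
#' @param frames a `size x size x n` numeric array in \[0, 1\], or a list of
#'   equally sized matrices.
#' @param frame_interval minutes between frames.
#' @param method fertilization method, `"IVF"` or `"ICSI"`.
#' @param video_id identifier string.
#' @return object of class `embryo_video`.
#' @export
embryo_video <- function(frames, frame_interval = 5, method = "IVF",
                         video_id = "embryo") {
  if (is.list(frames)) {
    stopifnot(length(frames) >= 1)
    dims <- vapply(frames, dim, integer(2))
    if (!all(dims == dims[, 1])) stop("all frames must have the same shape")
    frames <- array(unlist(frames), dim = c(dims[, 1], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3, dim(frames)[3] >= 1)
  structure(
    list(frames = frames, frame_interval = frame_interval,
         method = match.arg(method, c("IVF", "ICSI")), video_id = video_id),
    class = "embryo_video"
  )
}

#' @export
print.embryo_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<embryo_video %s: %d frames of %dx%d px, %s, %g min/frame>\n",
              x$video_id, d[3], d[1], d[2], x$method, x$frame_interval))
  invisible(x)
}

n_frames <- function(video) dim(video$frames)[3]

#' Render a synthetic embryo video from a cleavage schedule
#'
#' Each frame shows k disc-shaped blastomeres (k = stage at that frame) inside
#' a circular well; while the pronuclei are present two small high-intensity
#' discs are drawn inside the single cell; dark cytoplasmic speckles with
#' density proportional to `1 - morphology_score` encode fragmentation; frames
#' are independently degraded with probability `spec$stage_noise_rate` and
#' carry additive Gaussian noise.
#'
#' @param schedule a [sample_schedule()] result.
#' @param spec the governing [generator_spec()].
#' @param video_id identifier for the resulting video.
#' @param seed optional integer; when given, rendering is reseeded so the
#'   video is reproducible independently of the surrounding RNG state.
#' @return list with `video` (an [embryo_video()]), `truth` (the
#'   [ground_truth()] data frame) and `degraded` (logical per frame).
#' @export
render_video <- function(schedule, spec, video_id = "embryo", seed = NULL) {
  stopifnot(inherits(schedule, "cleavage_schedule"),
            inherits(spec, "generator_spec"))
  if (spec$image_size < 32) stop("image_size too small to place cell discs")
  if (!is.null(seed)) set.seed(seed)
  truth <- ground_truth(schedule)
  n <- nrow(truth)
  degraded <- runif(n) < spec$stage_noise_rate
  n_speckles <- as.integer(round(160 * (1 - schedule$morphology_score)))
  frames <- render_stack_cpp(
    spec$image_size, truth$stage, truth$pn == 1L, degraded,
    cell_layouts(), pn_disc_layout(), n_speckles,
    unname(render_params())
  )
  list(
    video = embryo_video(frames, frame_interval = 5, method = schedule$method,
                         video_id = video_id),
    truth = truth,
    degraded = degraded
  )
}

#' Simulate a dataset of embryo schedules and labels
#'
#' Draws `spec$n_videos` schedules, outcome labels and per-video render seeds
#' under `spec$seed`. Frames are not rendered here; use [render_embryo()] (or
#' [write_dataset()]) to materialize them. A spec plus its seed fully
#' determines the dataset, including every rendered pixel.
#'
#' @param spec a [generator_spec()].
#' @return object of class `embryo_dataset`: list with the spec and a list of
#'   per-video records (`video_id`, `schedule`, `labels`, `render_seed`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  videos <- vector("list", spec$n_videos)
  for (i in seq_len(spec$n_videos)) {
    schedule <- sample_schedule(spec)
    labels <- assign_outcome(schedule, spec)
    videos[[i]] <- list(
      video_id = sprintf("embryo_%04d", i),
      schedule = schedule,
      labels = labels,
      render_seed = sample.int(2147483646L, 1L)
    )
  }
  structure(list(spec = spec, videos = videos), class = "embryo_dataset")
}

#' Render one embryo of a simulated dataset
#'
#' @param dataset an [simulate_dataset()] result.
#' @param i video index.
#' @return as [render_video()].
#' @export
render_embryo <- function(dataset, i) {
  stopifnot(inherits(dataset, "embryo_dataset"),
            i >= 1, i <= length(dataset$videos))
  rec <- dataset$videos[[i]]
  render_video(rec$schedule, dataset$spec, video_id = rec$video_id,
               seed = rec$render_seed)
}

#' Write a synthetic dataset to disk
#'
#' Renders every video to a multi-page 8-bit grayscale TIFF, writes a
#' per-video frame-annotation CSV (`frame`, `stage`, `pn`) and a dataset
#' manifest CSV relating video files, fertilization method, morphokinetic
#' ground truth and outcome labels.
#'
#' @param spec a [generator_spec()], or an already materialized
#'   [simulate_dataset()] result.
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data frame, invisibly; also written to
#'   `manifest.csv` in `out_dir`.
#' @export
write_dataset <- function(spec, out_dir) {
  dataset <- if (inherits(spec, "embryo_dataset")) spec else
    simulate_dataset(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset$videos), function(i) {
    rec <- dataset$videos[[i]]
    rv <- render_embryo(dataset, i)
    tiff_file <- file.path(out_dir, paste0(rec$video_id, ".tiff"))
    ann_file <- file.path(out_dir, paste0(rec$video_id, "_frames.csv"))
    n <- n_frames(rv$video)
    pages <- lapply(seq_len(n), function(f) rv$video$frames[, , f])
    tiff::writeTIFF(pages, tiff_file, bits.per.sample = 8L,
                    compression = "none")
    write.csv(rv$truth, ann_file, row.names = FALSE)
    s <- rec$schedule
    data.frame(
      video_id = rec$video_id,
      file = basename(tiff_file),
      annotation_file = basename(ann_file),
      method = s$method,
      frame_count = s$frame_count,
      pn_appear_frame = s$pn_appear_frame,
      pnf_frame = s$pnf_frame,
      div2 = s$division_frames[1], div3 = s$division_frames[2],
      div4 = s$division_frames[3], div5 = s$division_frames[4],
      morphology_score = s$morphology_score,
      blastocyst = rec$labels[["blastocyst"]],
      usable = rec$labels[["usable"]]
    )
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset manifest written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return the manifest data frame.
#' @export
read_manifest <- function(dir) {
  read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
}

#' Read one embryo video (and its annotations) from a dataset directory
#'
#' @param dir dataset directory.
#' @param manifest_row one row of [read_manifest()].
#' @return list with `video` (an [embryo_video()]) and `truth` (data frame).
#' @export
read_embryo <- function(dir, manifest_row) {
  pages <- tiff::readTIFF(file.path(dir, manifest_row$file), all = TRUE)
  video <- embryo_video(pages, method = manifest_row$method,
                        video_id = manifest_row$video_id)
  truth <- read.csv(file.path(dir, manifest_row$annotation_file))
  list(video = video, truth = truth)
}
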