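# Temporal stream: PNF-anchored morphokinetic sequence classification.
#
# Each retained video contributes the 600 cell-stage tags at frames PNF-100
# through PNF+499. Anchoring on PNF removes the IVF/ICSI timing offset and
# gives every embryo the same sequence length. The sequence classifier
# encodes the window as binned stage-occupancy fractions (the frame number of
# each tag is implicit in its position after PNF alignment) and fits a
# single-hidden-layer neural network emitting the positive-class probability.

TEMPORAL_BEFORE <- 100L
TEMPORAL_AFTER <- 499L
TEMPORAL_LEN <- 600L

#' Extract the PNF-anchored temporal window
#'
#' @param tags stage-tag sequence: data frame with 0-based `frame` and
#'   `stage` covering frames `0..n-1`, or a plain stage vector.
#' @param pnf PNF frame index (0-based).
#' @param label optional binary outcome label to attach.
#' @return object of class `temporal_window`: list with `tags` (600 stage
#'   values covering frames PNF-100..PNF+499 inclusive), `pnf` and `label`.
#' @export
extract_temporal_window <- function(tags, pnf, label = NA_integer_) {
  stage <- if (is.data.frame(tags)) tags$stage else tags
  n <- length(stage)
  if (pnf < TEMPORAL_BEFORE || pnf + TEMPORAL_AFTER > n - 1L) {
    stop("PNF window out of range: pnf = ", pnf, ", frames = ", n)
  }
  idx <- (pnf - TEMPORAL_BEFORE):(pnf + TEMPORAL_AFTER) + 1L
  structure(list(tags = as.integer(stage[idx]), pnf = as.integer(pnf),
                 label = label),
            class = "temporal_window")
}

#' Temporal stream model configuration
#'
#' @param bins number of equal-width bins the 600-frame window is divided
#'   into for the stage-occupancy encoding (600 must be divisible by it).
#' @param size hidden units.
#' @param decay weight decay.
#' @param maxit training iterations.
#' @param encoding `"one_hot_stage"` (per-bin occupancy fractions of each
#'   stage) or `"integer_stage"` (per-bin mean stage value).
#' @param seed integer seed; training is deterministic given config and data.
#' @return list of class `temporal_config`.
#' @export
temporal_config <- function(bins = 24L, size = 6L, decay = 0.05,
                            maxit = 300L, encoding = "one_hot_stage",
                            seed = 1L) {
  stopifnot(bins >= 1, TEMPORAL_LEN %% bins == 0, size >= 1, decay >= 0)
  encoding <- match.arg(encoding, c("one_hot_stage", "integer_stage"))
  structure(list(bins = as.integer(bins), size = as.integer(size),
                 decay = decay, maxit = as.integer(maxit),
                 encoding = encoding, seed = as.integer(seed)),
            class = "temporal_config")
}

# windows: list of temporal_window -> n x 600 integer matrix
windows_matrix <- function(windows) {
  do.call(rbind, lapply(windows, function(w) {
    stopifnot(inherits(w, "temporal_window"), length(w$tags) == TEMPORAL_LEN)
    w$tags
  }))
}

encode_windows <- function(mat, config) {
  bins <- config$bins
  width <- TEMPORAL_LEN / bins
  if (config$encoding == "integer_stage") {
    enc <- sapply(seq_len(bins), function(b) {
      rowMeans(mat[, ((b - 1) * width + 1):(b * width), drop = FALSE])
    })
    if (is.null(dim(enc))) enc <- matrix(enc, nrow = 1)
    return(enc)
  }
  cols <- vector("list", bins * 5L)
  for (b in seq_len(bins)) {
    block <- mat[, ((b - 1) * width + 1):(b * width), drop = FALSE]
    for (s in 1:5) {
      cols[[(b - 1) * 5L + s]] <- rowMeans(block == s)
    }
  }
  do.call(cbind, cols)
}

#' Train the temporal stream model
#'
#' @param windows list of [extract_temporal_window()] results carrying
#'   labels, or a matrix with 600 columns (then `labels` is required).
#' @param labels optional binary labels overriding the windows' own.
#' @param config a [temporal_config()].
#' @return object of class `temporal_model`.
#' @export
train_temporal <- function(windows, labels = NULL, config = temporal_config()) {
  mat <- if (is.matrix(windows)) windows else windows_matrix(windows)
  if (ncol(mat) != TEMPORAL_LEN) {
    stop("temporal windows must have ", TEMPORAL_LEN, " entries")
  }
  if (is.null(labels)) {
    labels <- vapply(windows, function(w) as.integer(w$label), integer(1))
  }
  stopifnot(length(labels) == nrow(mat))
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class")
  }
  enc <- encode_windows(mat, config)
  set.seed(config$seed)
  fit <- nnet::nnet(enc, labels, size = config$size, decay = config$decay,
                    maxit = config$maxit, entropy = TRUE, trace = FALSE)
  structure(list(fit = fit, config = config), class = "temporal_model")
}

#' Score a temporal window
#'
#' @param model a [train_temporal()] model.
#' @param window an [extract_temporal_window()] result (or a list of them, or
#'   a matrix with 600 columns).
#' @return positive-class probability (blastocyst for the STEM task, usable
#'   blastocyst for STEM+), in \[0, 1\]; vectorized over windows.
#' @export
predict_temporal <- function(model, window) {
  stopifnot(inherits(model, "temporal_model"))
  mat <- if (inherits(window, "temporal_window")) {
    matrix(window$tags, nrow = 1)
  } else if (is.matrix(window)) {
    window
  } else {
    windows_matrix(window)
  }
  if (ncol(mat) != TEMPORAL_LEN) {
    stop("temporal window must have ", TEMPORAL_LEN, " entries, got ",
         ncol(mat))
  }
  enc <- encode_windows(mat, model$config)
  p <- as.numeric(predict(model$fit, enc))
  pmin(pmax(p, 0), 1)
}
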