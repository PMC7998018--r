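# Frame descriptors and frame embeddings.
#
# The frame classifiers (1-cell, PN presence, cell stage) operate on a small
# vector of morphological descriptors computed per frame in compiled code:
# global intensity moments, the thresholded cell mask (area, component count,
# two largest component areas, boundary length, intensity moments inside the
# mask) and the high-intensity mask that captures the pronuclei (area,
# component count, largest component). The spatial stream instead uses a
# dense pixel embedding (bilinear downsample) of each checkpoint frame.

FEATURE_MASK_THR <- 0.35
FEATURE_BRIGHT_THR <- 0.75

#' Morphological descriptors of video frames
#'
#' Computes, per frame, a 12-dimensional descriptor: global mean/sd intensity;
#' fraction, component count (8-connectivity, small components suppressed),
#' two largest component areas, boundary-pixel fraction and intensity mean/sd
#' of the cell mask (intensity > 0.35); and fraction, component count and
#' largest component of the high-intensity mask (> 0.75) that captures the
#' pronuclei.
#'
#' @param x an [embryo_video()], a `size x size x n` array, or a single frame
#'   matrix.
#' @return an `n x 12` matrix (one row per frame) with named columns.
#' @export
frame_features <- function(x) {
  if (inherits(x, "embryo_video")) x <- x$frames
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[1] == dim(x)[2])
  stack_features_cpp(x, FEATURE_MASK_THR, FEATURE_BRIGHT_THR, 15L, 3L)
}

#' Embed checkpoint frames into a feature matrix
#'
#' Embeds each of the 35 checkpoint frames with the package's default pixel
#' backbone: a bilinear downsample to 25 x 40 pixels flattened row-major into
#' a 1000-dimensional vector. The embedding is a pure, order-equivariant
#' function: identical frames give identical rows and permuting the input
#' frames permutes the rows identically. Alternative backbones can be
#' supplied as a function mapping one frame matrix to a numeric vector.
#'
#' @param frames list of 35 frame matrices, or a `size x size x 35` array.
#' @param backbone either the string `"pixel"` (default) or a function
#'   `function(frame) numeric(D)`.
#' @return an object of class `checkpoint_features`: a `35 x D` numeric
#'   matrix, rows in ascending checkpoint-frame order.
#' @export
embed_frames <- function(frames, backbone = "pixel") {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  if (length(frames) != 35L) {
    stop("exactly 35 checkpoint frames are required, got ", length(frames))
  }
  embed1 <- if (is.function(backbone)) {
    backbone
  } else if (identical(backbone, "pixel")) {
    function(fr) as.numeric(t(resize_bilinear_cpp(fr, 25L, 40L)))
  } else {
    stop("unknown backbone: ", backbone)
  }
  rows <- lapply(frames, embed1)
  d <- unique(lengths(rows))
  if (length(d) != 1) stop("backbone returned inconsistent dimensions")
  m <- do.call(rbind, rows)
  class(m) <- c("checkpoint_features", class(m))
  m
}
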