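# Spatial stream: frame embeddings at the five clinical observation
# checkpoints, classified with gradient boosting.
#
# The five checkpoints mirror the embryologist's bench schedule, expressed as
# frame offsets from PNF: fertilization check (PNF-75..PNF-69), syngamy check
# (PNF-3..PNF+3), early cleavage check (PNF+33..PNF+39), day-2 assessment
# (PNF+249..PNF+255) and day-3 assessment (PNF+493..PNF+499). Seven frames
# per checkpoint, 35 frames in total per embryo.

CHECKPOINT_OFFSETS <- list(
  fertilization = -75:-69,
  syngamy = -3:3,
  early_cleavage = 33:39,
  day2 = 249:255,
  day3 = 493:499
)

#' Frame indices of the five clinical observation checkpoints
#'
#' @param pnf PNF frame index (0-based); must be at least 75 so the
#'   fertilization-check window exists.
#' @return integer vector of 35 strictly increasing 0-based frame indices
#'   (five inclusive 7-frame windows).
#' @export
checkpoint_indices <- function(pnf) {
  if (pnf < 75) stop("pnf must be >= 75, got ", pnf)
  as.integer(pnf + unlist(CHECKPOINT_OFFSETS, use.names = FALSE))
}

#' Spatial stream model configuration
#'
#' Hyperparameters of the gradient-boosted classifier over the flattened
#' (checkpoint-major, row-major) 35 x D feature matrix.
#'
#' @param nrounds boosting rounds.
#' @param max_depth tree depth.
#' @param eta learning rate.
#' @param subsample,colsample_bytree row/column subsampling rates.
#' @param seed integer seed (single-threaded training is deterministic).
#' @return list of class `spatial_config`.
#' @export
spatial_config <- function(nrounds = 150L, max_depth = 3L, eta = 0.1,
                           subsample = 1, colsample_bytree = 0.3, seed = 1L) {
  structure(list(nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta,
                 subsample = subsample, colsample_bytree = colsample_bytree,
                 seed = as.integer(seed)),
            class = "spatial_config")
}

flatten_features <- function(m) {
  # row-major: checkpoint frame 1's D features, then frame 2's, ...
  as.numeric(t(m))
}

check_feature_matrix <- function(m, d = NULL) {
  if (!is.matrix(m) || nrow(m) != 35L) {
    stop("checkpoint feature matrix must have exactly 35 rows")
  }
  if (!is.null(d) && ncol(m) != d) {
    stop("feature dimension mismatch: got ", ncol(m), ", model expects ", d)
  }
  invisible(m)
}

#' Train the spatial stream model
#'
#' @param features list of 35 x D checkpoint feature matrices (one per
#'   embryo, from [embed_frames()]).
#' @param labels binary outcome labels, one per embryo.
#' @param config a [spatial_config()].
#' @return object of class `spatial_model`.
#' @export
train_spatial <- function(features, labels, config = spatial_config()) {
  stopifnot(length(features) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class")
  }
  lapply(features, check_feature_matrix)
  d <- ncol(features[[1]])
  x <- do.call(rbind, lapply(features, flatten_features))
  set.seed(config$seed)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = config$max_depth, eta = config$eta,
                  subsample = config$subsample,
                  colsample_bytree = config$colsample_bytree,
                  nthread = 1, seed = config$seed),
    data = xgboost::xgb.DMatrix(x, label = as.numeric(labels)),
    nrounds = config$nrounds
  )
  structure(list(fit = fit, d = d, config = config), class = "spatial_model")
}

#' Score a checkpoint feature matrix
#'
#' @param model a [train_spatial()] model.
#' @param features one 35 x D matrix, or a list of them.
#' @return positive-class probability in \[0, 1\]; vectorized over a list.
#' @export
predict_spatial <- function(model, features) {
  stopifnot(inherits(model, "spatial_model"))
  if (is.matrix(features)) features <- list(features)
  lapply(features, check_feature_matrix, d = model$d)
  x <- do.call(rbind, lapply(features, flatten_features))
  p <- as.numeric(predict(model$fit, xgboost::xgb.DMatrix(x)))
  pmin(pmax(p, 0), 1)
}
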