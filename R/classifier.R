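# Focal-loss frame classification.
#
# One classifier family serves all three per-frame tasks (1-cell vs
# multicell, PN presence, 5-way cell stage): a multinomial logistic model
# over the frame descriptors, trained by full-batch gradient descent on the
# focal loss. The focal loss down-weights well-classified frames so the rare
# stages (the 3-cell stage occupies only a few percent of frames) still
# contribute gradient.

#' Focal loss
#'
#' Per-sample loss `-w_y * (1 - p_y)^gamma * log(p_y)` where `p_y` is the
#' predicted probability of the true class and `w_y` its class weight; the
#' batch loss is the mean. With `gamma = 0` and unit weights this is exactly
#' the cross-entropy.
#'
#' @param prob numeric matrix of predicted class probabilities (rows =
#'   samples, columns = classes; each row sums to 1), or a vector for a
#'   single sample.
#' @param true integer vector of true class indices (1-based columns).
#' @param gamma focusing parameter, >= 0.
#' @param class_weights positive per-class weights (default all 1).
#' @param eps clamp for `log(0)`.
#' @return mean loss over samples.
#' @export
focal_loss <- function(prob, true, gamma = 2, class_weights = NULL,
                       eps = 1e-12) {
  if (is.vector(prob)) prob <- matrix(prob, nrow = 1)
  stopifnot(gamma >= 0, nrow(prob) == length(true),
            all(abs(rowSums(prob) - 1) < 1e-6))
  k <- ncol(prob)
  if (is.null(class_weights)) class_weights <- rep(1, k)
  stopifnot(length(class_weights) == k, all(class_weights > 0))
  p <- pmax(prob[cbind(seq_along(true), true)], eps)
  mean(-class_weights[true] * (1 - p)^gamma * log(p))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit a focal-loss multinomial logistic frame classifier
#'
#' Standardizes the descriptor columns and minimizes the mean focal loss with
#' momentum gradient descent (deterministic: zero initialization, full
#' batches). `class_weights = "inverse"` uses inverse-frequency weights
#' normalized to mean 1.
#'
#' @param x numeric descriptor matrix (rows = frames).
#' @param y class labels (factor, or anything coercible to one).
#' @param gamma focal focusing parameter.
#' @param class_weights `"inverse"`, `NULL` (unit weights) or a numeric
#'   vector, one weight per class level.
#' @param epochs gradient steps.
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param l2 ridge penalty on the weights.
#' @return object of class `frame_classifier`.
#' @export
fit_frame_classifier <- function(x, y, gamma = 2, class_weights = "inverse",
                                 epochs = 250, lr = 0.5, momentum = 0.9,
                                 l2 = 1e-4) {
  x <- as.matrix(x)
  y <- as.factor(y)
  lev <- levels(y)
  if (length(lev) < 2) stop("need at least two classes, got: ", lev)
  yi <- as.integer(y)
  n <- nrow(x)
  k <- length(lev)
  if (identical(class_weights, "inverse")) {
    freq <- tabulate(yi, k) / n
    if (any(freq == 0)) {
      stop("class absent from training data: ", lev[which(freq == 0)[1]])
    }
    cw <- (1 / freq) / mean(1 / freq)
  } else if (is.null(class_weights)) {
    cw <- rep(1, k)
  } else {
    stopifnot(length(class_weights) == k, all(class_weights > 0))
    cw <- class_weights
  }
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale < 1e-8] <- 1
  xs <- cbind(1, sweep(sweep(x, 2, center), 2, scale, "/"))
  w <- matrix(0, ncol(xs), k)
  v <- w
  eps <- 1e-12
  idx <- cbind(seq_len(n), yi)
  for (e in seq_len(epochs)) {
    p <- softmax_rows(xs %*% w)
    u <- pmax(p[idx], eps)
    om <- pmax(1 - u, eps)
    # d(loss)/d(p_true); chain through softmax gives the logit gradient
    g <- cw[yi] * (gamma * om^(gamma - 1) * log(u) - om^gamma / u)
    gz <- -(g * u) * p
    gz[idx] <- gz[idx] + g * u
    grad <- crossprod(xs, gz) / n + l2 * w
    v <- momentum * v - lr * grad
    w <- w + v
  }
  structure(
    list(weights = w, center = center, scale = scale, levels = lev,
         gamma = gamma, class_weights = cw, epochs = epochs, lr = lr,
         l2 = l2),
    class = "frame_classifier"
  )
}

#' Predict from a frame classifier
#'
#' @param object a [fit_frame_classifier()] model.
#' @param x descriptor matrix with the training columns.
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... unused.
#' @return factor of class labels, or a probability matrix.
#' @export
predict.frame_classifier <- function(object, x, type = c("class", "prob"),
                                     ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != length(object$center)) {
    stop("descriptor matrix has ", ncol(x), " columns; model expects ",
         length(object$center))
  }
  xs <- cbind(1, sweep(sweep(x, 2, object$center), 2, object$scale, "/"))
  p <- softmax_rows(xs %*% object$weights)
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  factor(object$levels[max.col(p, ties.method = "first")],
         levels = object$levels)
}

#' Configuration of the cell-stage classifier
#'
#' @param backbone name of the frame-embedding backbone; `"descriptor"` is
#'   the built-in morphological-descriptor front end.
#' @param focal_gamma focal focusing parameter, >= 0.
#' @param class_weights `"inverse"`, `NULL`, or 5 positive reals.
#' @param epochs,lr training scalars.
#' @param seed integer seed (training is deterministic given the config).
#' @return list of class `stage_classifier_config`.
#' @export
stage_classifier_config <- function(backbone = "descriptor", focal_gamma = 2,
                                    class_weights = "inverse", epochs = 250,
                                    lr = 0.5, seed = 1L) {
  stopifnot(focal_gamma >= 0)
  structure(list(backbone = backbone, focal_gamma = focal_gamma,
                 class_weights = class_weights, epochs = epochs, lr = lr,
                 seed = as.integer(seed)),
            class = "stage_classifier_config")
}

#' Train the five-way cell-stage classifier
#'
#' Learns the 1-, 2-, 3-, 4- and 5+-cell stages from labeled frames with the
#' focal loss, which counteracts the strong stage imbalance (the 3-cell stage
#' is by far the rarest).
#'
#' @param features descriptor matrix from [frame_features()] (rows = labeled
#'   frames).
#' @param stages integer vector of true stages in 1..5 (5 = the 5+ class).
#' @param config a [stage_classifier_config()].
#' @return object of class `stage_model`.
#' @export
train_stage_classifier <- function(features, stages,
                                   config = stage_classifier_config()) {
  stages <- as.integer(stages)
  stopifnot(all(stages %in% 1:5))
  missing <- setdiff(1:5, unique(stages))
  if (length(missing) > 0) {
    stop("cell stage(s) absent from training data: ",
         paste(missing, collapse = ", "))
  }
  set.seed(config$seed)
  clf <- fit_frame_classifier(
    features, factor(stages, levels = 1:5), gamma = config$focal_gamma,
    class_weights = config$class_weights, epochs = config$epochs,
    lr = config$lr
  )
  structure(list(classifier = clf, config = config), class = "stage_model")
}

#' Classify every frame of a video into a cell stage
#'
#' @param video an [embryo_video()] (or a precomputed descriptor matrix).
#' @param model a [train_stage_classifier()] model.
#' @return a stage-tag sequence: data frame with 0-based `frame` and `stage`
#'   in 1..5, one row per frame in order.
#' @export
classify_stages <- function(video, model) {
  stopifnot(inherits(model, "stage_model"))
  feats <- if (is.matrix(video)) video else frame_features(video)
  stage <- as.integer(as.character(predict(model$classifier, feats)))
  data.frame(frame = seq_len(nrow(feats)) - 1L, stage = stage)
}

#' Confusion matrix of stage predictions
#'
#' @param predicted,truth stage-tag sequences (data frames with `stage`), or
#'   plain stage vectors, of equal length.
#' @return list with `matrix` (5x5 counts, rows = true stage, columns =
#'   predicted stage) and `sensitivity` (diagonal over row totals; `NaN` for
#'   stages absent from the truth).
#' @export
stage_confusion <- function(predicted, truth) {
  p <- if (is.data.frame(predicted)) predicted$stage else predicted
  t <- if (is.data.frame(truth)) truth$stage else truth
  if (length(p) != length(t)) {
    stop("predicted and true sequences differ in length")
  }
  m <- table(factor(t, levels = 1:5), factor(p, levels = 1:5))
  m <- unclass(m)
  dimnames(m) <- list(true = 1:5, predicted = 1:5)
  list(matrix = m, sensitivity = diag(m) / rowSums(m))
}
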