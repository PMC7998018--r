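# End-to-end pipeline: synthetic dataset -> video preparation -> two streams
# -> weighted ensemble -> metrics.
#
# Mirrors the clinical workflow: a dedicated annotated subset trains the
# frame models (1-cell, PN, cell stage); the remaining videos are prepared
# with those models, screened, split 80/20, and the two streams are trained
# on the training split. The ensemble weight is searched on the evaluation
# split itself (the clinical procedure; see the methods vignette for the
# leakage caveat) and all metrics are reported on that split.

#' Pipeline configuration
#'
#' @param prep_videos number of videos reserved (with their ground-truth
#'   frame annotations) for training the frame models; they never enter the
#'   prediction analysis.
#' @param frame_stride stride for subsampling annotated frames when training
#'   the frame models.
#' @param stage a [stage_classifier_config()].
#' @param temporal a [temporal_config()].
#' @param spatial a [spatial_config()].
#' @param threshold decision threshold for binary calls.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(prep_videos = 60L, frame_stride = 3L,
                            stage = stage_classifier_config(),
                            temporal = temporal_config(),
                            spatial = spatial_config(),
                            threshold = 0.5) {
  structure(list(prep_videos = as.integer(prep_videos),
                 frame_stride = as.integer(frame_stride), stage = stage,
                 temporal = temporal, spatial = spatial,
                 threshold = threshold),
            class = "pipeline_config")
}

#' Prepare a simulated dataset for the two-stream models
#'
#' Renders every video; trains the frame models on an annotated subset; runs
#' video preparation (1-cell, PN, correction filter, PNF, screening) on the
#' rest; and for each retained video extracts the 600-frame temporal window
#' and the 35-frame checkpoint embeddings at the *estimated* PNF.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param config a [pipeline_config()].
#' @param seed integer seed controlling the prep subset, the 80/20 split and
#'   model training.
#' @return object of class `prepared_dataset` with the windows, embeddings,
#'   labels for both tasks, the trained prep models, the screening log and
#'   the train/validation split.
#' @export
prepare_analysis <- function(dataset, config = pipeline_config(), seed = 1L) {
  stopifnot(inherits(dataset, "embryo_dataset"))
  nv <- length(dataset$videos)
  if (config$prep_videos >= nv) {
    stop("prep_videos must be smaller than the dataset size")
  }
  set.seed(seed)
  prep_idx <- sort(sample.int(nv, config$prep_videos))
  analysis_idx <- setdiff(seq_len(nv), prep_idx)

  feat_list <- list()
  truth_list <- list()
  for (i in prep_idx) {
    rv <- render_embryo(dataset, i)
    feats <- frame_features(rv$video)
    keep <- seq(1, nrow(feats), by = config$frame_stride)
    feat_list[[length(feat_list) + 1L]] <- feats[keep, , drop = FALSE]
    truth_list[[length(truth_list) + 1L]] <- rv$truth[keep, , drop = FALSE]
  }
  models <- train_prep_models(do.call(rbind, feat_list),
                              do.call(rbind, truth_list),
                              stage_config = config$stage)

  windows <- list()
  embeddings <- list()
  ids <- character()
  blast <- integer()
  usable <- integer()
  screen_log <- data.frame(video_id = character(), retain = logical(),
                           reason = character(), pnf = integer(),
                           true_pnf = integer())
  for (i in analysis_idx) {
    rec <- dataset$videos[[i]]
    rv <- render_embryo(dataset, i)
    prep <- prepare_video(rv$video, models)
    screen_log <- rbind(screen_log, data.frame(
      video_id = rec$video_id, retain = prep$screen$retain,
      reason = prep$screen$reason,
      pnf = ifelse(prep$pnf$found, prep$pnf$frame, NA_integer_),
      true_pnf = rec$schedule$pnf_frame
    ))
    if (!prep$screen$retain) next
    tags <- classify_stages(prep$features, models$stage)
    windows[[length(windows) + 1L]] <-
      extract_temporal_window(tags, prep$pnf$frame)
    cps <- checkpoint_indices(prep$pnf$frame)
    embeddings[[length(embeddings) + 1L]] <-
      embed_frames(rv$video$frames[, , cps + 1L])
    ids <- c(ids, rec$video_id)
    blast <- c(blast, rec$labels[["blastocyst"]])
    usable <- c(usable, rec$labels[["usable"]])
  }
  n_ret <- length(ids)
  if (n_ret < 10) stop("fewer than 10 videos survived screening")
  val_n <- round(0.2 * n_ret)
  val_idx <- sort(sample.int(n_ret, val_n))
  structure(
    list(windows = windows, embeddings = embeddings, video_id = ids,
         labels = data.frame(blastocyst = blast, usable = usable),
         models = models, screen_log = screen_log,
         val_idx = val_idx, config = config, seed = seed),
    class = "prepared_dataset"
  )
}

#' Train the two streams and evaluate one prediction task
#'
#' @param prepared a [prepare_analysis()] result.
#' @param task `"stem"` (blastocyst vs nonblastocyst) or `"stem_plus"`
#'   (usable vs unusable blastocyst); the tasks differ only by label column.
#' @return list of class `pipeline_result` with the searched ensemble
#'   `weight`, `metrics` (ensemble [compute_metrics()] report plus `auc`),
#'   `temporal` and `spatial` single-stream metrics, and per-embryo
#'   `records`.
#' @export
evaluate_task <- function(prepared, task = c("stem", "stem_plus")) {
  stopifnot(inherits(prepared, "prepared_dataset"))
  task <- match.arg(task)
  labels <- if (task == "stem") prepared$labels$blastocyst else
    prepared$labels$usable
  n <- length(labels)
  val <- prepared$val_idx
  train <- setdiff(seq_len(n), val)
  if (length(unique(labels[train])) < 2) {
    stop("training split contains a single class for task ", task)
  }
  cfg <- prepared$config
  tm <- train_temporal(prepared$windows[train], labels[train],
                       config = cfg$temporal)
  sm <- train_spatial(prepared$embeddings[train], labels[train],
                      config = cfg$spatial)
  pt <- predict_temporal(tm, prepared$windows[val])
  ps <- predict_spatial(sm, prepared$embeddings[val])
  yv <- labels[val]
  sw <- search_weight(pt, ps, yv, threshold = cfg$threshold)
  pe <- ensemble_score(pt, ps, sw$weight)
  calls <- classify_call(pe, cfg$threshold)
  metrics <- compute_metrics(calls, yv)
  metrics$auc <- roc_auc(pe, yv)$auc
  stream_report <- function(p) {
    m <- compute_metrics(classify_call(p, cfg$threshold), yv)
    m$auc <- roc_auc(p, yv)$auc
    m
  }
  structure(
    list(task = task, weight = sw$weight, metrics = metrics,
         temporal = stream_report(pt), spatial = stream_report(ps),
         weight_grid = sw$grid,
         records = data.frame(
           video_id = prepared$video_id[val], temporal_score = pt,
           spatial_score = ps, ensemble_score = pe, call = calls,
           label = yv),
         models = list(temporal = tm, spatial = sm)),
    class = "pipeline_result"
  )
}

#' Run the full two-stream pipeline on a simulated dataset
#'
#' Convenience wrapper: [prepare_analysis()] then [evaluate_task()].
#'
#' @param dataset a [simulate_dataset()] result (or a [generator_spec()],
#'   which is materialized first).
#' @param task `"stem"` or `"stem_plus"`.
#' @param config a [pipeline_config()].
#' @param seed integer seed.
#' @return a `pipeline_result`, see [evaluate_task()].
#' @export
run_pipeline <- function(dataset, task = c("stem", "stem_plus"),
                         config = pipeline_config(), seed = 1L) {
  if (inherits(dataset, "generator_spec")) dataset <- simulate_dataset(dataset)
  prepared <- prepare_analysis(dataset, config = config, seed = seed)
  evaluate_task(prepared, task)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline %s: ensemble acc=%.3f auc=%.3f (w_temporal=%.2f) | temporal acc=%.3f auc=%.3f | spatial acc=%.3f auc=%.3f | n_val=%d>\n",
              x$task, x$metrics$accuracy, x$metrics$auc, x$weight,
              x$temporal$accuracy, x$temporal$auc, x$spatial$accuracy,
              x$spatial$auc, x$metrics$n))
  invisible(x)
}
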