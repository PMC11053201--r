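# End-to-end orchestration: synthetic (or on-disk) corpus -> train both
# branches -> frame-level video inference -> clip aggregation -> decision
# fusion -> metric reports.

#' Run configuration for the full pipeline
#'
#' @param sim A [sim_config()] describing the corpus (or `NULL` with
#'   `data_dir` pointing at keypoint JSON + WAV + manifest.csv on disk).
#' @param video A [video_config()]; default the desk-scale benchmark plan.
#' @param audio A [mobilenet_config()]; default the desk-scale benchmark plan.
#' @param split Training fraction of the clip-level stratified split, 0.8.
#' @param alpha_grid Video weights swept for linear fusion.
#' @param discount Dempster-Shafer source discount.
#' @param run_length Consecutive-frame rule for video aggregation, 15.
#' @param infer_stride Sliding-window stride for frame-level inference.
#' @param seed Root seed; per-stage seeds are derived from it.
#' @param out_dir Optional directory for CSV/JSON reports.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, video = NULL, audio = NULL, split = 0.8,
                       alpha_grid = c(0.6, 0.7, 0.8, 0.9), discount = 0,
                       run_length = 15, infer_stride = 5, seed = 1L,
                       out_dir = NULL) {
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)")
  seed <- as.integer(seed)
  sim <- sim %||% sim_config(seed = seed)
  video <- video %||% video_benchmark_config(seed = seed + 1L)
  audio <- audio %||% mobilenet_benchmark_config(seed = seed + 2L)
  structure(list(sim = sim, video = video, audio = audio, split = split,
                 alpha_grid = alpha_grid, discount = discount,
                 run_length = run_length, infer_stride = infer_stride,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognized keys mirror the constructor arguments, nested as `sim:`,
#' `video:` (`channels, lr, epochs, dropout, window, stride_infer, partition,
#' seed`, ...), `audio:` (`width_multiplier, input_size, lr, epochs`, ...)
#' and top-level `split, alpha_grid, discount, run_length, seed, out_dir`.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  sim <- do.call(sim_config, c(y$sim, if (is.null(y$sim$seed)) list(seed = seed)))
  video <- if (is.null(y$video)) NULL else do.call(video_config, y$video)
  audio <- if (is.null(y$audio)) NULL else do.call(mobilenet_config, y$audio)
  run_config(sim = sim, video = video, audio = audio,
             split = y$split %||% 0.8,
             alpha_grid = unlist(y$alpha_grid %||% c(0.6, 0.7, 0.8, 0.9)),
             discount = y$discount %||% 0,
             run_length = y$run_length %||% 15,
             infer_stride = y$infer_stride %||% 5,
             seed = seed, out_dir = y$out_dir)
}

# Stratified clip-level train/test split.
split_indices <- function(labels, split, seed) {
  set.seed(seed)
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    train <- c(train, sample(idx, round(length(idx) * split)))
  }
  list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
}

metric_row <- function(name, pred, truth) {
  m <- metrics(confusion(pred, truth))
  data.frame(model = name, sensitivity = m$sensitivity,
             specificity = m$specificity, accuracy = m$accuracy,
             precision = m$precision, f1 = m$f1)
}

#' Run the full multimodal pipeline
#'
#' Generates (or loads) the paired corpus, splits it 8:2 at clip level,
#' trains the two-stream skeleton network and the spectrogram classifier,
#' runs sliding-window frame inference and consecutive-frame aggregation on
#' the test clips, fuses the modality scores linearly (over the alpha grid)
#' and by Dempster's rule, and reports the five metrics for every model.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return A `pipeline_report`: list with `metrics` (one row per model:
#'   video, audio, each linear alpha, dempster), `alpha_sweep`, `scores`
#'   (per-clip table), `video_history`, `audio_history`, and `config`.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  say("generating corpus")
  ds <- gen_dataset(config$sim)
  labels <- ds$manifest$label
  sp <- split_indices(labels, config$split, config$seed + 10L)

  say("preparing skeleton streams")
  nseqs <- lapply(ds$skeletons, normalize_sequence)
  say("training video branch (", length(sp$train), " clips)")
  video_model <- train_video_model(nseqs[sp$train], config$video)

  say("video frame inference + aggregation")
  frame_preds <- lapply(nseqs[sp$test], predict_frames, model = video_model,
                        stride = config$infer_stride)
  video_scores <- aggregate_clips(frame_preds, run_length = config$run_length)

  say("audio features + training")
  mels <- lapply(ds$audio, logmel)
  audio_model <- train_audio_model(mels[sp$train], labels[sp$train], config$audio)
  audio_prob <- predict_audio(audio_model, mels[sp$test])
  audio_scores <- data.frame(clip_id = ds$manifest$clip_id[sp$test],
                             prob = audio_prob)

  say("fusing decisions")
  truth <- labels[sp$test]
  vtab <- data.frame(clip_id = video_scores$clip_id, prob = video_scores$prob)
  rows <- list(
    metric_row("video", video_scores$label, truth),
    metric_row("audio", decide(audio_prob), truth)
  )
  sweep_rows <- list()
  for (a in config$alpha_grid) {
    fused <- fuse_scores(vtab, audio_scores, "linear", alpha = a)
    rows[[length(rows) + 1L]] <-
      metric_row(sprintf("linear_alpha_%.1f", a), fused$label, truth)
    sweep_rows[[length(sweep_rows) + 1L]] <-
      cbind(alpha = a, rows[[length(rows)]][, -1])
  }
  fused_ds <- fuse_scores(vtab, audio_scores, "dempster",
                          discount = config$discount)
  rows[[length(rows) + 1L]] <- metric_row("dempster", fused_ds$label, truth)

  scores <- data.frame(clip_id = vtab$clip_id, truth = truth,
                       video_prob = vtab$prob, audio_prob = audio_scores$prob,
                       dempster_prob = fused_ds$fused)
  report <- structure(list(metrics = do.call(rbind, rows),
                           alpha_sweep = do.call(rbind, sweep_rows),
                           scores = scores,
                           video_history = video_model$history,
                           audio_history = audio_model$history,
                           config = config),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (held-out clips):\n")
  df <- x$metrics
  df[, -1] <- round(df[, -1], 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to disk
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(report$alpha_sweep, file.path(dir, "alpha_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(report$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(report$video_history, file.path(dir, "video_history.csv"),
                   row.names = FALSE)
  utils::write.csv(report$audio_history, file.path(dir, "audio_history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$metrics, file.path(dir, "metrics.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Fusion-benefit evaluation on the independent-error score regime
#'
#' Draws synthetic per-modality scores at the configured error rates for
#' `n_clips` clips, fuses them linearly and by Dempster's rule, and returns
#' the accuracies, optionally averaged over several seeds.
#'
#' @param config A [sim_config()].
#' @param n_clips Clips per draw (half fall), default `2 * n_per_class`.
#' @param alpha Video weight for the linear path.
#' @param discount Dempster discount.
#' @param seeds Integer vector of seeds to average over.
#' @return Data frame with one row per seed plus accuracy columns
#'   `video, audio, linear, dempster`.
#' @export
fusion_benefit <- function(config = sim_config(seed = 1L), n_clips = NULL,
                           alpha = 0.7, discount = 0, seeds = 1:5) {
  n_clips <- n_clips %||% (2L * config$n_per_class)
  labels <- rep(c("fall", "notfall"), length.out = n_clips)
  rows <- lapply(seeds, function(s) {
    sc <- gen_modality_scores(labels, config, seed = s)
    acc <- function(p) mean(decide(p) == sc$truth) * 100
    vtab <- data.frame(clip_id = sc$clip_id, prob = sc$video_prob)
    atab <- data.frame(clip_id = sc$clip_id, prob = sc$audio_prob)
    lin <- fuse_scores(vtab, atab, "linear", alpha = alpha)
    ds <- fuse_scores(vtab, atab, "dempster", discount = discount)
    data.frame(seed = s, video = acc(sc$video_prob), audio = acc(sc$audio_prob),
               linear = mean(lin$label == sc$truth) * 100,
               dempster = mean(ds$label == sc$truth) * 100)
  })
  do.call(rbind, rows)
}
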