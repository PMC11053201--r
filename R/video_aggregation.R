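# Frame-level to video-level decision: a clip depicts a fall when at least
# `run_length` consecutive frames are individually classified as fall.

#' Aggregate frame predictions into a video-level decision
#'
#' Frames are binarized at `frame_threshold`; the clip is labelled `"fall"`
#' iff some run of at least `run_length` consecutive frames is fall-positive.
#' The fall confidence is the maximal value among the mean probabilities of
#' the qualifying (maximal) runs. For clips with no qualifying run the
#' not-fall side still needs a fall probability for fusion, defined here as
#' the maximum sliding-window mean probability over all windows of
#' `run_length` frames — close to the decision boundary this degrades
#' gracefully instead of jumping to 0.
#'
#' @param frames A `frame_predictions` object or numeric vector of per-frame
#'   fall probabilities.
#' @param run_length Minimum consecutive fall frames, default 15.
#' @param frame_threshold Per-frame binarization threshold, default 0.5.
#' @return A `video_decision`: list with `clip_id`, `label`, `confidence` in
#'   the assigned label, `fall_prob` (the clip's fall probability for fusion:
#'   equal to `confidence` for fall clips and `1 - confidence` otherwise), and
#'   for fall clips the triggering `run_start`/`run_len`.
#' @examples
#' p <- c(rep(0.1, 30), rep(0.9, 20), rep(0.1, 25))
#' aggregate_frames(p)
#' @export
aggregate_frames <- function(frames, run_length = 15, frame_threshold = 0.5) {
  prob <- if (inherits(frames, "frame_predictions")) frames$prob else as.numeric(frames)
  clip_id <- if (inherits(frames, "frame_predictions")) frames$clip_id else NA_character_
  check_prob(prob, "frame probabilities")
  T_ <- length(prob)
  if (T_ < run_length) {
    stop("need at least run_length = ", run_length, " frames; got ", T_)
  }
  is_fall <- prob > frame_threshold
  runs <- rle(is_fall)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  qual <- which(runs$values & runs$lengths >= run_length)
  if (length(qual) > 0) {
    run_means <- vapply(qual, function(i) mean(prob[starts[i]:ends[i]]), numeric(1))
    best <- qual[which.max(run_means)]
    structure(list(clip_id = clip_id, label = "fall",
                   confidence = max(run_means), fall_prob = max(run_means),
                   run_start = starts[best], run_len = runs$lengths[best]),
              class = "video_decision")
  } else {
    # max mean over all length-run_length windows (exhaustive by cumsum)
    cs <- c(0, cumsum(prob))
    win_means <- (cs[(run_length + 1):(T_ + 1)] - cs[1:(T_ - run_length + 1)]) / run_length
    structure(list(clip_id = clip_id, label = "notfall",
                   confidence = 1 - max(win_means), fall_prob = max(win_means),
                   run_start = NA_integer_, run_len = NA_integer_),
              class = "video_decision")
  }
}

#' @export
print.video_decision <- function(x, ...) {
  cat(sprintf("Video decision %s: %s (confidence %.3f, fall prob %.3f)%s\n",
              ifelse(is.na(x$clip_id), "", paste0("'", x$clip_id, "'")),
              x$label, x$confidence, x$fall_prob,
              if (!is.na(x$run_start)) {
                sprintf(", run %d..%d", x$run_start, x$run_start + x$run_len - 1)
              } else ""))
  invisible(x)
}

#' Aggregate many clips into a score table
#'
#' @param frame_list List of `frame_predictions` (or probability vectors).
#' @inheritParams aggregate_frames
#' @return Data frame `clip_id, label, prob, run_start, run_len` where `prob`
#'   is the clip's fall confidence, ready for [fuse_scores()].
#' @export
aggregate_clips <- function(frame_list, run_length = 15, frame_threshold = 0.5) {
  rows <- lapply(frame_list, function(f) {
    d <- aggregate_frames(f, run_length, frame_threshold)
    data.frame(clip_id = d$clip_id, label = d$label, prob = d$fall_prob,
               run_start = d$run_start, run_len = d$run_len)
  })
  do.call(rbind, rows)
}
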