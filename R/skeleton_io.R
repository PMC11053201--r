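# COCO 17-keypoint order used throughout: 1 nose, 2 left eye, 3 right eye,
# 4 left ear, 5 right ear, 6 left shoulder, 7 right shoulder, 8 left elbow,
# 9 right elbow, 10 left wrist, 11 right wrist, 12 left hip, 13 right hip,
# 14 left knee, 15 right knee, 16 left ankle, 17 right ankle.

#' COCO keypoint names in skeleton order
#' @export
coco_keypoints <- function() {
  c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle")
}

# Natural-connection edge set H on the 17 COCO joints (1-indexed pairs):
# head chain, arms, legs, pelvis, and shoulder-hip trunk links.
coco_edges <- function() {
  rbind(
    c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 5),      # nose-eyes-ears
    c(4, 6), c(5, 7),                                 # ears to shoulders
    c(6, 7),                                          # shoulder girdle
    c(6, 8), c(8, 10), c(7, 9), c(9, 11),             # arms
    c(6, 12), c(7, 13),                               # trunk
    c(12, 13),                                        # pelvis
    c(12, 14), c(14, 16), c(13, 15), c(15, 17)        # legs
  )
}

#' Parse a 57-element pose prediction vector
#'
#' Splits the flat prediction record emitted per person and frame by an
#' anchor-based pose estimator into its named parts: bounding-box center
#' `(cx, cy)`, width and height, box and class confidences, then 17 keypoint
#' triples `(x, y, score)` occupying positions 7..57.
#'
#' @param raw Numeric vector of exactly 57 finite values in prediction order.
#' @return A `pose_vector`: list with `cx, cy, w, h, box_conf, class_conf` and
#'   a 17 x 3 `keypoints` matrix (columns `x, y, score`).
#' @examples
#' pv <- parse_pose_vector(c(160, 120, 40, 90, 0.9, 0.8, rep(0, 51)))
#' pv$keypoints[1, ]
#' @export
parse_pose_vector <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) != 57L) {
    stop("pose prediction vector must have exactly 57 elements ",
         "(6 box fields + 17 keypoint triples); got ", length(raw))
  }
  if (any(!is.finite(raw))) stop("pose vector contains non-finite values")
  conf <- raw[5:6]
  if (any(conf < 0 | conf > 1)) stop("box/class confidence outside [0, 1]")
  if (any(raw[3:4] < 0)) stop("box width/height must be non-negative")
  kp <- matrix(raw[7:57], ncol = 3, byrow = TRUE,
               dimnames = list(coco_keypoints(), c("x", "y", "score")))
  if (any(kp[, "score"] < 0 | kp[, "score"] > 1)) {
    stop("keypoint score outside [0, 1]")
  }
  structure(list(cx = raw[1], cy = raw[2], w = raw[3], h = raw[4],
                 box_conf = raw[5], class_conf = raw[6], keypoints = kp),
            class = "pose_vector")
}

#' Serialize a pose vector back to its 57-element layout
#' @param pv A `pose_vector`.
#' @return Numeric vector of length 57.
#' @export
serialize_pose_vector <- function(pv) {
  stopifnot(inherits(pv, "pose_vector"))
  c(pv$cx, pv$cy, pv$w, pv$h, pv$box_conf, pv$class_conf,
    as.numeric(t(pv$keypoints)))
}

#' Construct a skeleton sequence
#'
#' @param keypoints Numeric array `T x 17 x 3` (x, y, score) or a list of
#'   `pose_vector`s.
#' @param clip_id Clip identifier.
#' @param fps Frames per second, `> 0`.
#' @param label `"fall"`, `"notfall"`, or `NA` for unknown.
#' @return A `skeleton_sequence`: list with fields `clip_id`, `fps`,
#'   `keypoints` (T x 17 x 3 array), `label`, `n_frames`.
#' @export
skeleton_sequence <- function(keypoints, clip_id = "clip", fps = 25,
                              label = NA_character_) {
  if (is.list(keypoints)) {
    keypoints <- simplify2array(lapply(keypoints, function(p) p$keypoints))
    keypoints <- aperm(keypoints, c(3, 1, 2))
  }
  stopifnot(is.array(keypoints), length(dim(keypoints)) == 3)
  if (dim(keypoints)[2] != 17L || dim(keypoints)[3] != 3L) {
    stop("keypoint array must be T x 17 x 3; got ",
         paste(dim(keypoints), collapse = " x "))
  }
  if (dim(keypoints)[1] < 1L) stop("sequence needs at least one frame")
  if (fps <= 0) stop("fps must be positive")
  if (!is.na(label)) label <- as_fall_label(label)
  dimnames(keypoints) <- list(NULL, coco_keypoints(), c("x", "y", "score"))
  structure(list(clip_id = clip_id, fps = fps, keypoints = keypoints,
                 label = label, n_frames = dim(keypoints)[1]),
            class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("Skeleton sequence '%s': %d frames x 17 joints @ %g fps, label %s\n",
              x$clip_id, x$n_frames, x$fps,
              ifelse(is.na(x$label), "unknown", x$label)))
  invisible(x)
}

#' Read a keypoint sequence from JSON or CSV
#'
#' JSON dialect: a list of `{"frame": int, "pose": [57 floats]}` or
#' `{"frame": int, "keypoints": [[x, y, score] x 17]}` records. CSV dialect:
#' one row per frame with header
#' `frame,cx,cy,w,h,box_conf,class_conf,kx1,ky1,ks1,...,ks17`.
#' Frames are ordered by frame index; blank frames (every keypoint score below
#' `blank_threshold`, e.g. no person visible) are eliminated and their indices
#' recorded in attribute `"eliminated_frames"`.
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; default guesses from the extension.
#' @param blank_threshold Score below which a keypoint counts as missing;
#'   a frame is blank when all 17 scores fall below it. Default 0.05.
#' @inheritParams skeleton_sequence
#' @return A `skeleton_sequence`.
#' @export
read_sequence <- function(path, format = c("auto", "json", "csv"),
                          clip_id = NULL, fps = 25, label = NA_character_,
                          blank_threshold = 0.05) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (is.null(clip_id)) clip_id <- sub("\\.[^.]+$", "", basename(path))
  if (format == "json") {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(recs) == 0) stop("empty keypoint file: ", path)
    frame_idx <- vapply(recs, function(r) as.numeric(r$frame), numeric(1))
    kp_list <- lapply(recs, function(r) {
      if (!is.null(r$pose)) {
        parse_pose_vector(unlist(r$pose))$keypoints
      } else if (!is.null(r$keypoints)) {
        m <- do.call(rbind, lapply(r$keypoints, unlist))
        if (!is.numeric(m) || nrow(m) != 17L || ncol(m) != 3L) {
          stop("frame ", r$frame, ": keypoints must be 17 triples (x, y, score)")
        }
        m
      } else {
        stop("frame ", r$frame, ": record has neither 'pose' nor 'keypoints'")
      }
    })
  } else {
    df <- utils::read.csv(path)
    if (nrow(df) == 0) stop("empty keypoint file: ", path)
    kcols <- setdiff(names(df), "frame")
    if (!identical(length(kcols) %in% c(51L, 57L), TRUE)) {
      stop("CSV must have frame + 51 keypoint or 57 pose columns; got ",
           length(kcols), " data columns in ", path)
    }
    frame_idx <- df$frame
    kp_list <- lapply(seq_len(nrow(df)), function(i) {
      row <- as.numeric(df[i, kcols])
      if (any(!is.finite(row))) stop("non-finite value at row ", i, " of ", path)
      if (length(row) == 57L) parse_pose_vector(row)$keypoints
      else matrix(row, ncol = 3, byrow = TRUE)
    })
  }
  ord <- order(frame_idx)
  kp <- aperm(simplify2array(kp_list[ord]), c(3, 1, 2))
  blank <- apply(kp[, , 3, drop = FALSE], 1, function(s) all(s < blank_threshold))
  eliminated <- frame_idx[ord][blank]
  kp <- kp[!blank, , , drop = FALSE]
  if (dim(kp)[1] == 0) stop("all frames in ", path, " are blank")
  seq <- skeleton_sequence(kp, clip_id = clip_id, fps = fps, label = label)
  attr(seq, "eliminated_frames") <- eliminated
  seq
}

#' Write a keypoint sequence as JSON
#'
#' Inverse of the keypoints-only JSON dialect of [read_sequence()].
#' @param seq A `skeleton_sequence`.
#' @param path Output path.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  recs <- lapply(seq_len(seq$n_frames), function(t) {
    list(frame = t, keypoints = unname(apply(seq$keypoints[t, , ], 1, as.list,
                                             simplify = FALSE)))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build the 17-joint skeleton graph with a partition strategy
#'
#' Constructs the undirected natural-connection graph on the COCO joints and
#' the stack of normalized adjacency matrices the graph convolution uses. The
#' neighborhood of a joint is itself plus its 1-hop neighbors; every entry is
#' normalized by the neighborhood size of the receiving joint, so the
#' partition matrices stacked together form a row-stochastic operator.
#'
#' Strategies: `"uni-label"` keeps the whole neighborhood in one subset
#' (a single degree-normalized A + I matrix); `"distance"` splits self
#' (distance 0) from 1-hop neighbors; `"spatial"` splits into root,
#' centripetal (neighbor closer to the skeleton center than the root joint)
#' and centrifugal (farther) subsets, with closeness measured by hop distance
#' to the center joint.
#'
#' @param partition_strategy One of `"spatial"`, `"uni-label"`, `"distance"`.
#' @param center Center joint index for the spatial strategy; default 1 (nose).
#' @return A `skeleton_graph`: list with `n_joints`, `edges` (matrix of index
#'   pairs), `partition_strategy`, `adjacency` (17 x 17 x P array of
#'   normalized matrices), and `support` (unnormalized A + I pattern).
#' @export
build_skeleton_graph <- function(partition_strategy = c("spatial", "uni-label", "distance"),
                                 center = 1L) {
  partition_strategy <- match.arg(partition_strategy)
  n <- 17L
  edges <- coco_edges()
  A <- matrix(0, n, n)
  A[edges] <- 1
  A <- A + t(A)
  A[A > 1] <- 1
  support <- A + diag(n)                       # self always in B(v)
  deg <- rowSums(support)                      # |B(v_i)| = Z normalization
  hop <- hop_distance(A)
  parts <- switch(partition_strategy,
    "uni-label" = list(support),
    "distance" = list(diag(n), A),
    "spatial" = {
      r <- hop[, center]
      root <- diag(n)
      centripetal <- matrix(0, n, n)
      centrifugal <- matrix(0, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (A[i, j] == 1) {
          if (r[j] < r[i]) centripetal[i, j] <- 1
          else if (r[j] > r[i]) centrifugal[i, j] <- 1
          else root[i, j] <- 1                 # equal distance joins the root subset
        }
      }
      list(root, centripetal, centrifugal)
    })
  adjacency <- vapply(parts, function(P) P / deg, matrix(0, n, n))
  dim(adjacency) <- c(n, n, length(parts))
  structure(list(n_joints = n, edges = edges,
                 partition_strategy = partition_strategy,
                 adjacency = adjacency, support = support, hop = hop),
            class = "skeleton_graph")
}

# All-pairs hop distances by BFS-style matrix powers (n = 17, trivial cost).
hop_distance <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n)
  for (k in seq_len(n)) {
    reach <- reach %*% (A + diag(n))
    newly <- which(reach > 0 & !is.finite(d))
    if (length(newly) == 0) break
    d[newly] <- k
  }
  d
}

#' Export the skeleton edge list as text
#' @param graph A `skeleton_graph`.
#' @param path Output path.
#' @export
write_graph_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "skeleton_graph"))
  nm <- coco_keypoints()
  df <- data.frame(from = graph$edges[, 1], to = graph$edges[, 2],
                   from_name = nm[graph$edges[, 1]], to_name = nm[graph$edges[, 2]])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Center and scale-normalize a skeleton sequence
#'
#' Per frame, joint coordinates are translated so the hip midpoint sits at the
#' origin; the whole sequence is then divided by its median torso length (hip
#' midpoint to shoulder midpoint distance), making the representation
#' invariant to image translation and uniform scale. Keypoint scores pass
#' through untouched. Coordinates are image-pixel convention: origin top-left,
#' y increasing downward.
#'
#' Joints with score 0 (occluded, coordinates 0) are excluded from the hip and
#' shoulder midpoints when the paired joint is visible; fully occluded
#' reference pairs fall back to the frame's visible-joint centroid.
#'
#' @param seq A `skeleton_sequence`.
#' @return A `normalized_sequence`: list with `data` (T x 17 x C array, C = 2
#'   coordinates + 1 score channel), `scale`, `clip_id`, `fps`, `label`.
#' @export
normalize_sequence <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  kp <- seq$keypoints
  T_ <- dim(kp)[1]
  scores <- kp[, , 3, drop = FALSE]
  if (all(scores == 0) || all(kp[, , 1:2] == 0)) {
    stop("sequence has no valid joints to normalize")
  }
  hip_idx <- c(12L, 13L)
  sho_idx <- c(6L, 7L)
  out <- kp
  torso <- rep(NA_real_, T_)
  for (t in seq_len(T_)) {
    fr <- kp[t, , ]
    vis <- fr[, 3] > 0
    midpoint <- function(idx) {
      use <- idx[vis[idx]]
      if (length(use) > 0) colMeans(fr[use, 1:2, drop = FALSE])
      else if (any(vis)) colMeans(fr[vis, 1:2, drop = FALSE])
      else c(0, 0)
    }
    hip <- midpoint(hip_idx)
    sho <- midpoint(sho_idx)
    out[t, , 1] <- ifelse(vis, fr[, 1] - hip[1], 0)
    out[t, , 2] <- ifelse(vis, fr[, 2] - hip[2], 0)
    torso[t] <- sqrt(sum((sho - hip)^2))
  }
  scale <- stats::median(torso[torso > 0], na.rm = TRUE)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  out[, , 1:2] <- out[, , 1:2] / scale
  structure(list(data = out, scale = scale, clip_id = seq$clip_id,
                 fps = seq$fps, label = seq$label, n_frames = T_),
            class = "normalized_sequence")
}

#' Motion stream: frame-to-frame coordinate differences
#'
#' Produces the second ST-GCN input stream: for every frame `t >= 2` the
#' coordinate channels hold `x(t) - x(t-1)`; frame 1 is all zeros so the shape
#' is preserved. The score channel holds the per-frame minimum of the two
#' scores entering each difference.
#'
#' @param nseq A `normalized_sequence` with at least 2 frames.
#' @return A `normalized_sequence` of identical shape holding differences.
#' @export
motion_stream <- function(nseq) {
  stopifnot(inherits(nseq, "normalized_sequence"))
  x <- nseq$data
  T_ <- dim(x)[1]
  if (T_ < 2) stop("motion stream needs at least 2 frames")
  d <- array(0, dim = dim(x), dimnames = dimnames(x))
  d[2:T_, , 1:2] <- x[2:T_, , 1:2] - x[1:(T_ - 1), , 1:2]
  d[2:T_, , 3] <- pmin(x[2:T_, , 3], x[1:(T_ - 1), , 3])
  out <- nseq
  out$data <- d
  out
}
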