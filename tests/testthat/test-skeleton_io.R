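test_that("pose vectors parse positionally and reject malformed records", {
  pv <- parse_pose_vector(rep(0, 57))
  expect_true(all(pv$keypoints == 0))
  expect_equal(pv$box_conf, 0)
  raw <- c(160, 120, 40, 90, 0.9, 0.8, 10, 20, 0.9, rep(0, 48))
  pv2 <- parse_pose_vector(raw)
  expect_equal(unname(pv2$keypoints[1, ]), c(10, 20, 0.9))
  expect_equal(pv2$cx, 160)
  expect_error(parse_pose_vector(rep(0, 51)), "57")
  expect_error(parse_pose_vector(c(rep(0, 56), NaN)), "non-finite")
  expect_error(parse_pose_vector(c(0, 0, -1, 0, rep(0, 53))), "non-negative")
})

test_that("serialization is the inverse of parsing", {
  set.seed(2)
  raw <- c(rnorm(2, 100, 10), runif(2, 10, 50), runif(2),
           as.numeric(t(cbind(rnorm(17, 150, 30), rnorm(17, 120, 40), runif(17)))))
  expect_equal(serialize_pose_vector(parse_pose_vector(raw)), raw)
})

test_that("sequences read from JSON and CSV with blank-frame elimination", {
  seq0 <- toy_sequence(T_ = 75, jitter = 1, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_sequence(seq0, path)
  back <- read_sequence(path)
  expect_equal(back$n_frames, 75)
  expect_equal(back$keypoints[, , 1:2], seq0$keypoints[, , 1:2],
               tolerance = 1e-9, ignore_attr = TRUE)

  # blank 3 frames -> eliminated and recorded
  kp <- seq0$keypoints
  kp[c(10, 20, 30), , ] <- 0
  blanked <- skeleton_sequence(kp)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_sequence(blanked, path2)
  back2 <- read_sequence(path2)
  expect_equal(back2$n_frames, 72)
  expect_equal(attr(back2, "eliminated_frames"), c(10, 20, 30))

  # CSV dialect (keypoints-only columns)
  path3 <- withr::local_tempfile(fileext = ".csv")
  flat <- t(vapply(seq_len(5), function(t) as.numeric(t(seq0$keypoints[t, , ])),
                   numeric(51)))
  df <- data.frame(frame = 1:5, flat)
  names(df) <- c("frame", paste0(rep(c("kx", "ky", "ks"), 17),
                                 rep(1:17, each = 3)))
  write.csv(df, path3, row.names = FALSE)
  back3 <- read_sequence(path3, format = "csv")
  expect_equal(back3$n_frames, 5)
  expect_equal(back3$keypoints[3, 5, 2], seq0$keypoints[3, 5, 2])

  # degenerate inputs error instead of yielding empty sequences
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("[]", empty)
  expect_error(read_sequence(empty), "empty")
  expect_error(read_sequence("/nonexistent/path.json"), "not found")
})

test_that("skeleton graph is connected, symmetric and degree-normalized", {
  g <- build_skeleton_graph("uni-label")
  A <- g$support - diag(17)
  expect_true(all(A == t(A)))
  expect_true(all(is.finite(fallfusion:::hop_distance(A))))   # connected
  # dense-matrix oracle: uni-label = (A + I) normalized by neighborhood size
  expect_equal(g$adjacency[, , 1], (A + diag(17)) / rowSums(A + diag(17)))
})

test_that("partition stacks tile the neighborhood and stay row-stochastic", {
  for (strat in c("uni-label", "distance", "spatial")) {
    g <- build_skeleton_graph(strat)
    stacked <- apply(g$adjacency, c(1, 2), sum)
    expect_equal((stacked > 0) + 0, (g$support > 0) + 0,
                 info = strat)                       # same support pattern
    expect_equal(rowSums(stacked), rep(1, 17), tolerance = 1e-12)
    # constant signal is preserved by the stacked operator
    expect_equal(as.numeric(stacked %*% rep(3.7, 17)), rep(3.7, 17),
                 tolerance = 1e-12)
  }
  expect_equal(dim(build_skeleton_graph("spatial")$adjacency)[3], 3)
  expect_error(build_skeleton_graph("banana"))
})

test_that("graph edge list exports as readable text", {
  g <- build_skeleton_graph()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph_edgelist(g, path)
  df <- read.delim(path)
  expect_equal(nrow(df), nrow(g$edges))
  expect_true("left_hip" %in% c(df$from_name, df$to_name))
})

test_that("normalization is invariant to translation and uniform scale", {
  set.seed(21)
  for (rep in 1:5) {
    seq0 <- toy_sequence(T_ = 12, jitter = 4, seed = rep)
    n0 <- normalize_sequence(seq0)
    shifted <- seq0
    shifted$keypoints[, , 1] <- shifted$keypoints[, , 1] + 5
    shifted$keypoints[, , 2] <- shifted$keypoints[, , 2] + 9
    expect_equal(normalize_sequence(shifted)$data, n0$data, tolerance = 1e-9)
    scaled <- seq0
    scaled$keypoints[, , 1:2] <- scaled$keypoints[, , 1:2] * 2
    expect_equal(normalize_sequence(scaled)$data, n0$data, tolerance = 1e-9)
  }
  # already centered with unit torso is a fixed point
  seq1 <- toy_sequence(T_ = 5, jitter = 0)
  n1 <- normalize_sequence(seq1)
  renorm <- skeleton_sequence(n1$data, fps = seq1$fps)
  expect_equal(normalize_sequence(renorm)$data, n1$data, tolerance = 1e-9)
  # hip midpoint sits at the origin every frame
  hips <- apply(n1$data[, 12:13, 1:2], c(1, 3), mean)
  expect_equal(max(abs(hips)), 0, tolerance = 1e-9)
  zero <- skeleton_sequence(array(0, c(3, 17, 3)))
  expect_error(normalize_sequence(zero), "no valid joints")
})

test_that("motion stream is the first difference with a zero leading frame", {
  seq0 <- toy_sequence(T_ = 10)
  n0 <- normalize_sequence(seq0)
  const <- motion_stream(n0)
  expect_equal(dim(const$data), dim(n0$data))
  expect_equal(max(abs(const$data[, , 1:2])), 0, tolerance = 1e-9)
  # linear motion -> constant difference from frame 2 on
  lin <- n0
  for (t in 1:10) lin$data[t, , 1] <- lin$data[t, , 1] + 0.25 * t
  m <- motion_stream(lin)
  expect_equal(max(abs(m$data[1, , 1:2])), 0)
  expect_equal(as.numeric(m$data[2:10, , 1]), rep(0.25, 9 * 17), tolerance = 1e-9)
  # second difference of a quadratic is constant from frame 3 on
  quad <- n0
  for (t in 1:10) quad$data[t, , 2] <- quad$data[t, , 2] + 0.1 * t^2
  m2 <- motion_stream(motion_stream(quad))
  expect_equal(as.numeric(m2$data[3:10, , 2]), rep(0.2, 8 * 17), tolerance = 1e-9)
  short <- n0
  short$data <- short$data[1, , , drop = FALSE]
  short$n_frames <- 1
  expect_error(motion_stream(short), "at least 2")
})
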