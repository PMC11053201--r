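test_that("spatial graph convolution equals the brute-force neighborhood sum", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(2:6, 1)
    # random connected graph: random spanning chain plus extra edges
    edges <- cbind(1:(n - 1), 2:n)
    if (n > 2 && runif(1) < 0.7) {
      extra <- sort(sample(1:n, 2))
      edges <- rbind(edges, extra)
    }
    A <- matrix(0, n, n); A[edges] <- 1; A <- pmin(A + t(A), 1)
    feats <- array(rnorm(4 * n * 3), dim = c(4, n, 3))
    for (strat in c("uni-label", "distance", "spatial")) {
      g <- graph_from_edges(edges, n, strat)
      P <- dim(g$adjacency)[3]
      weights <- lapply(seq_len(P), function(p) matrix(rnorm(3 * 2), 3, 2))
      got <- spatial_graph_conv(feats, g, weights)
      want <- oracle_graph_conv(feats, A, strat, weights)
      expect_equal(got, want, tolerance = 1e-10, info = paste(strat, n))
    }
  }
})

test_that("graph convolution limiting cases behave analytically", {
  # isolated single node with identity weight: output equals input
  g1 <- graph_from_edges(matrix(numeric(0), 0, 2), 1, "uni-label")
  f1 <- array(rnorm(5 * 1 * 2), dim = c(5, 1, 2))
  expect_equal(spatial_graph_conv(f1, g1, list(diag(2))), f1)
  # 3-node path, uni-label, identity weights: degree-normalized (A+I) product
  g3 <- graph_from_edges(rbind(c(1, 2), c(2, 3)), 3, "uni-label")
  f3 <- array(0, dim = c(1, 3, 1)); f3[1, , 1] <- c(1, 2, 3)
  A <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))
  want <- (A / rowSums(A)) %*% c(1, 2, 3)
  expect_equal(as.numeric(spatial_graph_conv(f3, g3, list(matrix(1, 1, 1)))),
               as.numeric(want), tolerance = 1e-12)
  # constant input with partition weights summing to identity stays constant
  gs <- graph_from_edges(rbind(c(1, 2), c(2, 3)), 3, "spatial")
  fc <- array(2.5, dim = c(2, 3, 1))
  w <- list(matrix(1), matrix(1), matrix(1))   # sum of partitions is stochastic
  expect_equal(as.numeric(spatial_graph_conv(fc, gs, w)), rep(2.5, 6),
               tolerance = 1e-12)
  expect_error(spatial_graph_conv(array(0, c(2, 5, 2)), g3, list(diag(2))),
               "joint count")
})

test_that("ST-GCN layers preserve or halve the temporal length", {
  g <- build_skeleton_graph()
  set.seed(4)
  x <- array(rnorm(75 * 17 * 2), dim = c(75, 17, 2))
  y1 <- stgcn_layer(x, g, out_channels = 3, stride = 1)
  expect_equal(dim(y1), c(75, 17, 3))
  y2 <- stgcn_layer(x, g, out_channels = 3, stride = 2)
  expect_equal(dim(y2), c(38, 17, 3))          # ceil(75/2)
  expect_error(stgcn_layer(x, g, 3, stride = 3), "stride")
  expect_error(stgcn_layer(x, g, 3, temporal_kernel = 4), "odd")
})

test_that("the nine-layer stride plan maps 75 frames to 19", {
  cfg <- video_config(channels = rep(2, 9), epochs = 1)
  g <- build_skeleton_graph()
  set.seed(8)
  model <- fallfusion:::build_video_model(cfg, g)
  x <- array(rnorm(2 * 75 * 17 * 2), dim = c(2, 75, 17, 2))
  want_T <- c(75, 75, 75, 38, 38, 38, 19, 19, 19)
  for (i in 1:9) {
    x <- model$joint_net$layers[[i]]$fwd(x, training = FALSE)
    expect_equal(dim(x)[2], want_T[i])
  }
  expect_equal(dim(x)[2], ceiling(ceiling(75 / 2) / 2))
})

test_that("binary cross-entropy matches direct evaluation and is non-negative", {
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)
  expect_equal(bce_loss(c(1, 0, 1), c(0.9, 0.2, 0.6)),
               bce_loss(c(0, 1, 1), c(0.2, 0.9, 0.6)))   # order invariance
  set.seed(12)
  for (rep in 1:20) {
    expect_gte(bce_loss(rbinom(5, 1, 0.5), runif(5)), 0)
  }
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
  expect_error(bce_loss(c(1, 2), c(0.5, 0.5)), "0 or 1")
  expect_error(bce_loss(1, 0.5, eps = 1e-7), NA)
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(7)
  g3 <- graph_from_edges(rbind(c(1, 2), c(2, 3)), 3, "uni-label")
  l1 <- fallfusion:::stgcn_layer_module(2, 3, g3$adjacency, temporal_kernel = 3,
                                        stride = 1, dropout = 0)
  net <- fallfusion:::nn_sequential(l1, fallfusion:::nn_global_pool(),
                                    fallfusion:::nn_dense(3, 1))
  xs <- array(rnorm(2 * 6 * 3 * 2), c(2, 6, 3, 2))
  y <- c(1, 0)
  loss_fn <- function() {
    p <- fallfusion:::sigmoid(drop(net$fwd(xs, training = TRUE)))
    bce_loss(y, p)
  }
  p <- fallfusion:::sigmoid(drop(net$fwd(xs, TRUE)))
  net$bwd(matrix((p - y) / 2, nrow = 1))
  for (l in fallfusion:::collect_layers(net)) {
    for (nm in l$param_names) {
      P <- get(nm, envir = l)
      G <- get(paste0("d", nm), envir = l)
      for (k in sample(seq_along(P), min(5, length(P)))) {
        eps <- 1e-5
        P[k] <- P[k] + eps; assign(nm, P, envir = l); f1 <- loss_fn()
        P[k] <- P[k] - 2 * eps; assign(nm, P, envir = l); f2 <- loss_fn()
        P[k] <- P[k] + eps; assign(nm, P, envir = l)
        num <- (f1 - f2) / (2 * eps)
        expect_lt(abs(num - G[k]) / max(1e-4, abs(num) + abs(G[k])), 1e-4)
      }
    }
  }
})

test_that("the two-stream head is a probability and is permutation-equivariant", {
  cfg <- video_config(channels = rep(2, 9), epochs = 1, dropout = 0)
  edges <- fallfusion:::coco_edges()
  g <- graph_from_edges(edges, 17, "spatial", center = 1)
  set.seed(19)
  perm <- sample(17)                       # new index of each old joint
  pedges <- cbind(perm[edges[, 1]], perm[edges[, 2]])
  gp <- graph_from_edges(pedges, 17, "spatial", center = perm[1])
  set.seed(99); m1 <- fallfusion:::build_video_model(cfg, g)
  set.seed(99); m2 <- fallfusion:::build_video_model(cfg, gp)
  set.seed(5)
  x <- list(joint = array(rnorm(2 * 20 * 17 * 3), c(2, 20, 17, 3)),
            motion = array(rnorm(2 * 20 * 17 * 3), c(2, 20, 17, 3)))
  xp <- list(joint = array(0, dim(x$joint)), motion = array(0, dim(x$motion)))
  xp$joint[, , perm, ] <- x$joint
  xp$motion[, , perm, ] <- x$motion
  p1 <- m1$fwd(x, training = FALSE)
  p2 <- m2$fwd(xp, training = FALSE)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("training is reproducible and reduces the loss on separable data", {
  cfg0 <- sim_config(seed = 77, n_per_class = 5, score_dropout = 0)
  set.seed(1)
  seqs <- lapply(1:10, function(i) {
    gen_skeleton(if (i <= 5) "fall" else "notfall", cfg0, seed = i,
                 clip_id = paste0("c", i))
  })
  nseqs <- lapply(seqs, normalize_sequence)
  vcfg <- video_config(channels = rep(2, 9), epochs = 4, batch_size = 5,
                       seed = 123)
  m1 <- train_video_model(nseqs, vcfg)
  m2 <- train_video_model(nseqs, vcfg)
  expect_equal(m1$history$loss, m2$history$loss)           # same seed, same run
  expect_lt(tail(m1$history$loss, 1), m1$history$loss[1])  # learning happens
  single <- nseqs[1:5]
  expect_error(train_video_model(single, vcfg), "both classes")
})

test_that("frame predictions cover every frame via sliding windows", {
  cfg0 <- sim_config(seed = 78, n_per_class = 2)
  sk <- gen_skeleton("notfall", cfg0, seed = 4)
  nseq <- normalize_sequence(sk)
  vcfg <- video_config(channels = rep(2, 9), epochs = 1, window = 30,
                       stride_infer = 7, seed = 3)
  g <- build_skeleton_graph()
  set.seed(3)
  model <- fallfusion:::build_video_model(vcfg, g)
  fp <- predict_frames(model, nseq)
  expect_equal(length(fp$prob), 75)
  expect_true(all(fp$prob >= 0 & fp$prob <= 1))
  # window equal to the whole sequence: one probability everywhere
  fp2 <- predict_frames(model, nseq, window = 75)
  expect_equal(length(unique(fp2$prob)), 1)
  short <- nseq
  short$data <- short$data[1:10, , , drop = FALSE]
  short$n_frames <- 10
  expect_error(predict_frames(model, short, window = 30), "shorter")
})
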