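# Two-stream spatio-temporal graph convolutional network over skeleton
# sequences: per-frame graph convolution on the joint graph, temporal
# convolution over corresponding joints across frames, nine layers per
# stream, global pooling and a fully connected sigmoid head.

#' Build partitioned adjacency for an arbitrary small graph
#'
#' Generalizes [build_skeleton_graph()] to any undirected graph, mainly so the
#' graph convolution can be validated against brute-force sums on tiny graphs.
#'
#' @param edges Two-column matrix of 1-indexed undirected edges.
#' @param n_nodes Number of nodes.
#' @inheritParams build_skeleton_graph
#' @return A `skeleton_graph`-classed object (generic node set).
#' @export
graph_from_edges <- function(edges, n_nodes,
                             partition_strategy = c("spatial", "uni-label", "distance"),
                             center = 1L) {
  partition_strategy <- match.arg(partition_strategy)
  A <- matrix(0, n_nodes, n_nodes)
  if (length(edges) > 0) {
    edges <- matrix(edges, ncol = 2)
    A[edges] <- 1
    A <- A + t(A)
    A[A > 1] <- 1
  }
  support <- A + diag(n_nodes)
  deg <- rowSums(support)
  parts <- switch(partition_strategy,
    "uni-label" = list(support),
    "distance" = list(diag(n_nodes), A),
    "spatial" = {
      r <- hop_distance(A)[, center]
      root <- diag(n_nodes)
      centripetal <- matrix(0, n_nodes, n_nodes)
      centrifugal <- matrix(0, n_nodes, n_nodes)
      for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
        if (A[i, j] == 1) {
          if (r[j] < r[i]) centripetal[i, j] <- 1
          else if (r[j] > r[i]) centrifugal[i, j] <- 1
          else root[i, j] <- 1
        }
      }
      list(root, centripetal, centrifugal)
    })
  adjacency <- vapply(parts, function(P) P / deg, matrix(0, n_nodes, n_nodes))
  dim(adjacency) <- c(n_nodes, n_nodes, length(parts))
  structure(list(n_joints = n_nodes, edges = edges,
                 partition_strategy = partition_strategy,
                 adjacency = adjacency, support = support),
            class = "skeleton_graph")
}

#' Spatial graph convolution over a skeleton feature map
#'
#' For every frame `t` and joint `i`, the output feature is the sum over the
#' 1-hop neighborhood (self included) of the input features, normalized by the
#' neighborhood size and weighted per partition subset:
#' `f_out(v_ti) = sum_j f_in(v_tj) w(subset(j)) / Z_ti(v_tj)`. Equivalent to
#' per-partition normalized-adjacency matrix products, which is how it is
#' computed here.
#'
#' @param features Numeric array `T x V x C_in`.
#' @param graph A `skeleton_graph` with matching node count.
#' @param weights List of `C_in x C_out` matrices, one per partition subset.
#' @param bias Optional length-`C_out` bias.
#' @return Array `T x V x C_out`.
#' @export
spatial_graph_conv <- function(features, graph, weights, bias = NULL) {
  stopifnot(inherits(graph, "skeleton_graph"), length(dim(features)) == 3)
  if (dim(features)[2] != graph$n_joints) {
    stop("feature joint count (", dim(features)[2],
         ") does not match graph (", graph$n_joints, ")")
  }
  P <- dim(graph$adjacency)[3]
  if (length(weights) != P) {
    stop("need one weight matrix per partition subset (", P, ")")
  }
  d <- dim(features)
  out_ch <- ncol(weights[[1]])
  out <- array(0, dim = c(d[1], d[2], out_ch))
  for (p in seq_len(P)) {
    A <- graph$adjacency[, , p]
    for (t in seq_len(d[1])) {
      out[t, , ] <- out[t, , ] + (A %*% features[t, , ]) %*% weights[[p]]
    }
  }
  if (!is.null(bias)) out <- sweep(out, 3, bias, `+`)
  out
}

## ---- ST-GCN layer module --------------------------------------------------

# GCN sub-block (graph conv + BN + ReLU) then TCN sub-block (temporal conv +
# BN + dropout), residual connection, final ReLU. Dropout sits after the
# second normalization so batch statistics are estimated on clean
# activations and remain valid at inference time.
stgcn_layer_module <- function(in_ch, out_ch, adjacency, temporal_kernel = 9,
                               stride = 1, dropout = 0.5, residual = TRUE) {
  if (!stride %in% c(1, 2)) stop("stride must be 1 or 2")
  e <- new_layer("stgcn_layer")
  e$gcn <- nn_graph_conv(in_ch, out_ch, adjacency)
  e$bn1 <- nn_batchnorm(out_ch)
  e$relu1 <- nn_relu()
  e$drop <- nn_dropout(dropout)
  e$tcn <- nn_temporal_conv(out_ch, out_ch, kernel = temporal_kernel,
                            stride = stride)
  e$bn2 <- nn_batchnorm(out_ch)
  e$relu2 <- nn_relu()
  e$res <- if (!residual) {
    NULL
  } else if (in_ch == out_ch && stride == 1) {
    "identity"
  } else {
    nn_temporal_conv(in_ch, out_ch, kernel = 1, stride = stride)
  }
  e$sublayers <- Filter(function(l) is.environment(l),
                        list(e$gcn, e$bn1, e$drop, e$tcn, e$bn2, e$res,
                             e$relu1, e$relu2))
  e$fwd <- function(x, training = TRUE) {
    y <- e$relu1$fwd(e$bn1$fwd(e$gcn$fwd(x, training), training), training)
    y <- e$drop$fwd(e$bn2$fwd(e$tcn$fwd(y, training), training), training)
    r <- if (is.null(e$res)) 0
         else if (identical(e$res, "identity")) x
         else e$res$fwd(x, training)
    e$relu2$fwd(y + r, training)
  }
  e$bwd <- function(dy) {
    dsum <- e$relu2$bwd(dy)
    dx_main <- e$tcn$bwd(e$bn2$bwd(e$drop$bwd(dsum)))
    dx_main <- e$gcn$bwd(e$bn1$bwd(e$relu1$bwd(dx_main)))
    if (is.null(e$res)) dx_main
    else if (identical(e$res, "identity")) dx_main + dsum
    else dx_main + e$res$bwd(dsum)
  }
  e
}

#' Apply one ST-GCN layer to a feature map
#'
#' Convenience functional form (randomly initialized weights from the current
#' RNG state): graph convolution sub-block then temporal convolution
#' sub-block, each followed by normalization and a nonlinearity, with a
#' residual connection. With stride 2 the temporal length halves
#' (`ceiling(T/2)` under symmetric padding).
#'
#' @param features Array `T x V x C_in`.
#' @param graph A `skeleton_graph`.
#' @param out_channels Output channel count.
#' @param temporal_kernel Odd temporal kernel size (frames), default 9.
#' @param stride Temporal stride, 1 or 2.
#' @param residual Keep the residual connection (default TRUE).
#' @return Array `T' x V x out_channels`.
#' @export
stgcn_layer <- function(features, graph, out_channels, temporal_kernel = 9,
                        stride = 1, residual = TRUE) {
  d <- dim(features)
  mod <- stgcn_layer_module(d[3], out_channels, graph$adjacency,
                            temporal_kernel, stride, dropout = 0,
                            residual = residual)
  x <- array(aperm(features, c(3, 1, 2)), dim = c(d[3], d[1], d[2], 1))
  y <- mod$fwd(x, training = TRUE)
  aperm(array(y, dim = dim(y)[1:3]), c(2, 3, 1))
}

#' Configuration for the two-stream video model
#'
#' The network has exactly nine ST-GCN layers per stream; temporal strides of
#' layers 4 and 7 are 2 (halving the frame dimension), all others 1. The two
#' streams (joint coordinates and frame-difference motion) have independent
#' weights and are merged by a fully connected layer on their pooled features.
#'
#' @param channels Nine output channel counts; the canonical plan
#'   `64,64,64,128,128,128,256,256,256`.
#' @param in_channels Input channels per joint (2 coordinates; 3 adds score).
#' @param temporal_kernel Odd temporal kernel, default 9.
#' @param dropout Dropout rate inside every layer, default 0.5.
#' @param lr Adam learning rate, default 1e-3.
#' @param epochs Training epochs, default 60.
#' @param batch_size Minibatch size, default 16.
#' @param partition Partition strategy for the skeleton graph.
#' @param window,stride_infer Sliding-window length and stride used by
#'   [predict_frames()] (frames), defaults 45 and 1.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return A `video_config` list.
#' @export
video_config <- function(channels = c(64, 64, 64, 128, 128, 128, 256, 256, 256),
                         in_channels = 2, temporal_kernel = 9, dropout = 0.5,
                         lr = 1e-3, epochs = 60, batch_size = 16,
                         partition = "spatial", window = 45, stride_infer = 1,
                         seed = 1L) {
  if (length(channels) != 9) stop("the network has exactly nine layers")
  structure(list(channels = channels, in_channels = in_channels,
                 temporal_kernel = temporal_kernel, dropout = dropout,
                 lr = lr, epochs = epochs, batch_size = batch_size,
                 partition = partition, window = window,
                 stride_infer = stride_infer, seed = as.integer(seed),
                 strides = c(1, 1, 1, 2, 1, 1, 2, 1, 1)),
            class = "video_config")
}

#' Desk-scale configuration for the synthetic benchmark
#'
#' Same nine-layer/stride structure, dropout and learning rate as the full
#' plan, with a narrow channel plan and fewer epochs sized to the synthetic
#' corpus.
#' @inheritParams video_config
#' @param ... Passed on to [video_config()].
#' @export
video_benchmark_config <- function(epochs = 8, batch_size = 16, seed = 1L, ...) {
  video_config(channels = c(4, 4, 4, 8, 8, 8, 16, 16, 16),
               epochs = epochs, batch_size = batch_size, seed = seed, ...)
}

# Build one stream: nine stgcn layers + global pool.
build_stream <- function(config, adjacency) {
  layers <- list()
  in_ch <- config$in_channels
  for (i in 1:9) {
    layers[[i]] <- stgcn_layer_module(
      in_ch, config$channels[i], adjacency,
      temporal_kernel = config$temporal_kernel,
      stride = config$strides[i], dropout = config$dropout,
      # the very first layer has no residual (channel jump from raw input)
      residual = i > 1
    )
    in_ch <- config$channels[i]
  }
  layers[[10]] <- nn_global_pool()
  do.call(nn_sequential, layers)
}

# Two-stream model container.
build_video_model <- function(config, graph) {
  e <- new_layer("two_stream")
  e$config <- config
  e$graph <- graph
  e$joint_net <- build_stream(config, graph$adjacency)
  e$motion_net <- build_stream(config, graph$adjacency)
  c_last <- config$channels[9]
  e$head <- nn_dense(2 * c_last, 1)
  e$c_last <- c_last
  e$sublayers <- list(e$joint_net, e$motion_net, e$head)
  e$fwd <- function(x, training = TRUE) {
    zj <- e$joint_net$fwd(x$joint, training)          # C x N
    zm <- e$motion_net$fwd(x$motion, training)
    z <- rbind(zj, zm)
    drop(sigmoid(e$head$fwd(z, training)))            # N probabilities
  }
  e$bwd <- function(dlogit) {                         # gradient wrt head logit
    dz <- e$head$bwd(matrix(dlogit, nrow = 1))
    e$joint_net$bwd(dz[seq_len(e$c_last), , drop = FALSE])
    e$motion_net$bwd(dz[e$c_last + seq_len(e$c_last), , drop = FALSE])
    invisible(NULL)
  }
  class(e) <- c("video_model", class(e))
  e
}

# list of normalized_sequence -> batched [C, T, V, N] arrays for both streams
stack_streams <- function(nseqs, in_channels = 2) {
  T_ <- unique(vapply(nseqs, function(s) s$n_frames, numeric(1)))
  if (length(T_) != 1) stop("all sequences must share the same frame count")
  ch <- seq_len(in_channels)
  joint <- vapply(nseqs, function(s) aperm(s$data[, , ch, drop = FALSE], c(3, 1, 2)),
                  array(0, dim = c(in_channels, T_, 17)))
  motion <- vapply(nseqs, function(s) {
    aperm(motion_stream(s)$data[, , ch, drop = FALSE], c(3, 1, 2))
  }, array(0, dim = c(in_channels, T_, 17)))
  list(joint = joint, motion = motion)
}

#' Forward pass of the two-stream network
#'
#' Runs both streams through their nine-layer stacks, pools, concatenates and
#' maps to a fall probability through the fully connected sigmoid head.
#'
#' @param model A trained (or freshly built) `video_model`.
#' @param nseqs List of `normalized_sequence` objects with equal frame counts.
#' @return Numeric vector of fall probabilities, one per sequence.
#' @export
two_stream_forward <- function(model, nseqs) {
  stopifnot(inherits(model, "video_model"))
  x <- stack_streams(nseqs, model$config$in_channels)
  p <- model$fwd(x, training = FALSE)
  as.numeric(p)
}

#' Train the two-stream skeleton classifier
#'
#' Adam on binary cross-entropy over minibatches of paired joint/motion
#' streams. Deterministic given `config$seed` (initialization, shuffling and
#' dropout all draw from the seeded RNG).
#'
#' @param nseqs List of `normalized_sequence` objects carrying labels.
#' @param config A [video_config()].
#' @param graph Skeleton graph; default built from `config$partition`.
#' @param verbose Print per-epoch loss.
#' @return A `video_model` with attached `history` (data.frame epoch, loss).
#' @export
train_video_model <- function(nseqs, config = video_config(), graph = NULL,
                              verbose = FALSE) {
  labels <- vapply(nseqs, function(s) s$label, character(1))
  if (length(nseqs) == 0) stop("empty training set")
  y <- as.numeric(labels == "fall")
  if (length(unique(y)) < 2) {
    stop("training set must contain both classes (fall and notfall)")
  }
  if (is.null(graph)) graph <- build_skeleton_graph(config$partition)
  set.seed(config$seed)
  model <- build_video_model(config, graph)
  opt <- adam_optimizer(model, lr = config$lr)
  x_all <- stack_streams(nseqs, config$in_channels)
  n <- length(nseqs)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    total <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- list(joint = x_all$joint[, , , idx, drop = FALSE],
                 motion = x_all$motion[, , , idx, drop = FALSE])
      p <- model$fwd(xb, training = TRUE)
      total <- total + bce_loss(y[idx], p) * length(idx)
      model$bwd((p - y[idx]) / length(idx))           # d BCE / d logit
      opt$step()
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = total / n))
    if (verbose) message(sprintf("epoch %d  loss %.4f", epoch, total / n))
  }
  refresh_bn_stats(model, function() model$fwd(x_all, training = TRUE))
  model$history <- history
  model
}

#' Per-frame fall probabilities by sliding-window inference
#'
#' Classifies overlapping windows of the sequence and assigns to every frame
#' the probability of the window whose center lies nearest, so the output
#' covers all `T` frames.
#'
#' @param model A `video_model`.
#' @param nseq A `normalized_sequence` at least as long as `window`.
#' @param window Window length in frames; default from the model config.
#' @param stride Window stride at inference; default from the model config.
#' @return A `frame_predictions` object: list with `clip_id`, `prob`
#'   (length-`T` vector), `window`, `stride`.
#' @export
predict_frames <- function(model, nseq, window = NULL, stride = NULL) {
  stopifnot(inherits(model, "video_model"), inherits(nseq, "normalized_sequence"))
  window <- window %||% model$config$window
  stride <- stride %||% model$config$stride_infer
  T_ <- nseq$n_frames
  if (T_ < window) {
    stop("sequence (", T_, " frames) shorter than inference window (", window, ")")
  }
  starts <- unique(c(seq(1, T_ - window + 1, by = stride), T_ - window + 1))
  subs <- lapply(starts, function(s) {
    out <- nseq
    out$data <- nseq$data[s:(s + window - 1), , , drop = FALSE]
    out$n_frames <- window
    out
  })
  p_win <- two_stream_forward(model, subs)
  centers <- starts + (window - 1) / 2
  prob <- vapply(seq_len(T_), function(t) {
    p_win[which.min(abs(centers - t))]
  }, numeric(1))
  structure(list(clip_id = nseq$clip_id, prob = prob,
                 window = window, stride = stride),
            class = "frame_predictions")
}
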