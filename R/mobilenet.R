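# MobileNetV2 for single-channel spectrogram images: depthwise-separable
# convolutions arranged in inverted residual bottlenecks with linear
# projections, a 1x1 conv to the feature head, global average pooling,
# dropout and a k-way softmax classifier.

# Standard channel rounding: nearest multiple of `divisor`, never below the
# divisor and never more than 10% below the requested value.
make_divisible <- function(v, divisor = 8, min_value = divisor) {
  new_v <- max(min_value, (floor(v + divisor / 2) %/% divisor) * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  new_v
}

# Bottleneck schedule: expansion t, output channels c, repeats n, stride s
# (stride applies to the first repeat of a row, the rest use 1).
mobilenet_schedule <- function() {
  data.frame(t = c(1, 6, 6, 6, 6, 6, 6),
             c = c(16, 24, 32, 64, 96, 160, 320),
             n = c(1, 2, 3, 4, 3, 3, 1),
             s = c(1, 2, 2, 2, 1, 2, 1))
}

#' MobileNetV2 configuration
#'
#' @param width_multiplier Scales every channel count (rounded to multiples
#'   of 8); 1 is the published architecture, smaller values give desk-scale
#'   variants.
#' @param input_size Side length of the square single-channel input image.
#' @param classes Output classes, default 2 (fall / notfall).
#' @param dropout Dropout before the classifier, default 0.2.
#' @param lr Adam learning rate, default 1e-3.
#' @param weight_decay L2 regularization coefficient for Adam, default 1e-4.
#' @param epochs,batch_size,seed Training loop controls.
#' @return A `mobilenet_config` list including the resolved per-stage channel
#'   counts (`stem`, `schedule$c_scaled`, `head`).
#' @export
mobilenet_config <- function(width_multiplier = 1, input_size = 224,
                             classes = 2, dropout = 0.2, lr = 1e-3,
                             weight_decay = 1e-4, epochs = 20, batch_size = 16,
                             seed = 1L) {
  sched <- mobilenet_schedule()
  sched$c_scaled <- vapply(sched$c, function(c) {
    make_divisible(c * width_multiplier)
  }, numeric(1))
  structure(list(width_multiplier = width_multiplier, input_size = input_size,
                 classes = classes, dropout = dropout, lr = lr,
                 weight_decay = weight_decay, epochs = epochs,
                 batch_size = batch_size, seed = as.integer(seed),
                 stem = make_divisible(32 * width_multiplier),
                 head = if (width_multiplier > 1) {
                   make_divisible(1280 * width_multiplier)
                 } else 1280,
                 schedule = sched),
            class = "mobilenet_config")
}

#' Desk-scale audio benchmark configuration
#'
#' Width 0.25 at 32 x 32 input: the same bottleneck structure at a size a
#' single CPU trains in minutes on the synthetic corpus. Training from random
#' initialization on a small corpus needs a slightly hotter learning rate
#' (3e-3) and more epochs than the full-scale fine-tuning setting.
#' @param epochs Training epochs, default 45.
#' @param lr Adam learning rate, default 3e-3.
#' @param ... Passed to [mobilenet_config()].
#' @export
mobilenet_benchmark_config <- function(epochs = 45, lr = 3e-3, ...) {
  mobilenet_config(width_multiplier = 0.25, input_size = 32, epochs = epochs,
                   lr = lr, ...)
}

# One inverted residual block: 1x1 expand (omitted when t = 1), 3x3 depthwise
# (stride s), 1x1 linear projection; residual when shapes are preserved.
inverted_residual <- function(in_ch, out_ch, stride, expansion) {
  e <- new_layer("inverted_residual")
  hidden <- in_ch * expansion
  e$use_res <- (stride == 1 && in_ch == out_ch)
  blocks <- list()
  if (expansion != 1) {
    blocks <- c(blocks, list(nn_conv2d(in_ch, hidden, kernel = 1, pad = 0),
                             nn_batchnorm(hidden), nn_relu(6)))
  }
  blocks <- c(blocks, list(
    nn_conv2d(hidden, hidden, kernel = 3, stride = stride, groups = hidden),
    nn_batchnorm(hidden), nn_relu(6),
    nn_conv2d(hidden, out_ch, kernel = 1, pad = 0),
    nn_batchnorm(out_ch)                                 # linear projection
  ))
  e$body <- do.call(nn_sequential, blocks)
  e$sublayers <- list(e$body)
  e$fwd <- function(x, training = TRUE) {
    y <- e$body$fwd(x, training)
    if (e$use_res) y + x else y
  }
  e$bwd <- function(dy) {
    dx <- e$body$bwd(dy)
    if (e$use_res) dx + dy else dx
  }
  e
}

#' Build a MobileNetV2 model
#'
#' Stem 3x3 conv (stride 2), seven inverted-residual bottleneck stages, 1x1
#' conv to the feature head, global average pool, dropout, and a dense
#' softmax classifier.
#'
#' @param config A [mobilenet_config()].
#' @return A `mobilenet_model` (network container with `$fwd`/`$bwd`).
#' @export
build_mobilenet <- function(config) {
  stopifnot(inherits(config, "mobilenet_config"))
  layers <- list(nn_conv2d(1, config$stem, kernel = 3, stride = 2),
                 nn_batchnorm(config$stem), nn_relu(6))
  in_ch <- config$stem
  sched <- config$schedule
  for (r in seq_len(nrow(sched))) {
    for (rep in seq_len(sched$n[r])) {
      layers[[length(layers) + 1L]] <- inverted_residual(
        in_ch, sched$c_scaled[r],
        stride = if (rep == 1) sched$s[r] else 1,
        expansion = sched$t[r])
      in_ch <- sched$c_scaled[r]
    }
  }
  layers <- c(layers, list(nn_conv2d(in_ch, config$head, kernel = 1, pad = 0),
                           nn_batchnorm(config$head), nn_relu(6),
                           nn_global_pool()))
  e <- new_layer("mobilenet")
  e$config <- config
  e$features <- do.call(nn_sequential, layers)
  e$drop <- nn_dropout(config$dropout)
  e$classifier <- nn_dense(config$head, config$classes)
  e$sublayers <- list(e$features, e$drop, e$classifier)
  e$fwd <- function(x, training = TRUE) {
    z <- e$features$fwd(x, training)                     # head_ch x N
    logits <- e$classifier$fwd(e$drop$fwd(z, training), training)
    softmax_cols(logits)                                 # classes x N
  }
  e$bwd <- function(dlogits) {
    e$features$bwd(e$drop$bwd(e$classifier$bwd(dlogits)))
    invisible(NULL)
  }
  class(e) <- c("mobilenet_model", class(e))
  e
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  ez <- exp(z)
  sweep(ez, 2, colSums(ez), `/`)
}

#' Forward pass: class probabilities for spectrogram images
#'
#' @param model A `mobilenet_model` (or a `mobilenet_config`, in which case a
#'   freshly initialized model is built from the current RNG state).
#' @param images A `size x size` matrix, a `size x size x N` array, or a list
#'   of matrices / `mel_spectrogram`s (resized as needed).
#' @return `N x 2` matrix of probabilities, columns `fall`, `notfall`; rows
#'   sum to 1.
#' @export
mobilenet_forward <- function(model, images) {
  if (inherits(model, "mobilenet_config")) model <- build_mobilenet(model)
  stopifnot(inherits(model, "mobilenet_model"))
  x <- images_to_batch(images, model$config$input_size)
  p <- model$fwd(x, training = FALSE)
  out <- t(p)
  colnames(out) <- c("fall", "notfall")
  out
}

# Accept flexible image input, return [1, H, W, N].
images_to_batch <- function(images, size) {
  if (inherits(images, "mel_spectrogram")) images <- list(images)
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3) {
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  }
  mats <- lapply(images, function(im) {
    if (inherits(im, "mel_spectrogram")) im <- mel_to_image(im, size)
    if (!all(dim(im) == c(size, size))) {
      stop("input image is ", paste(dim(im), collapse = "x"),
           " but the model expects ", size, "x", size)
    }
    im
  })
  x <- array(0, dim = c(1, size, size, length(mats)))
  for (i in seq_along(mats)) x[1, , , i] <- mats[[i]]
  x
}

#' Spatial-size trace through the network
#'
#' Input side lengths seen by the seven bottleneck stages and the final 1x1
#' conv, for a square input: with a 224 input this is
#' 112, 112, 56, 28, 14, 14, 7, 7.
#'
#' @param input_size Input side length, default 224.
#' @return Integer vector of length 8.
#' @export
mobilenet_spatial_trace <- function(input_size = 224) {
  conv_out <- function(s, stride) (s + 2 * 1 - 3) %/% stride + 1   # 3x3, pad 1
  sizes <- integer(8)
  s <- conv_out(input_size, 2)                                     # after stem
  sched <- mobilenet_schedule()
  for (r in seq_len(nrow(sched))) {
    sizes[r] <- s
    s <- conv_out(s, sched$s[r])                                   # first repeat
  }
  sizes[8] <- s
  sizes
}

#' Number of trainable parameters in a network
#' @param model A model container (e.g. from [build_mobilenet()]).
#' @return Total count of weight, bias and normalization parameters.
#' @export
count_parameters <- function(model) {
  n_parameters(model)
}

#' Train the audio spectrogram classifier
#'
#' Adam with L2 weight decay on the softmax cross-entropy over minibatches of
#' resized spectrogram images. Deterministic given `config$seed`.
#'
#' @param images List of `mel_spectrogram`s or `input_size` square matrices.
#' @param labels Aligned `"fall"`/`"notfall"` labels.
#' @param config A [mobilenet_config()].
#' @param verbose Print per-epoch loss.
#' @return A `mobilenet_model` with attached `history`.
#' @export
train_audio_model <- function(images, labels, config = mobilenet_config(),
                              verbose = FALSE) {
  labels <- as_fall_label(labels)
  if (length(images) == 0) stop("empty training set")
  if (length(unique(labels)) < 2) {
    stop("training set must contain both classes (fall and notfall)")
  }
  set.seed(config$seed)
  model <- build_mobilenet(config)
  opt <- adam_optimizer(model, lr = config$lr,
                        weight_decay = config$weight_decay)
  x_all <- images_to_batch(images, config$input_size)
  y <- ifelse(labels == "fall", 1L, 2L)                  # class index
  n <- length(labels)
  onehot <- matrix(0, config$classes, n)
  onehot[cbind(y, seq_len(n))] <- 1
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    total <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      p <- model$fwd(x_all[, , , idx, drop = FALSE], training = TRUE)
      total <- total - sum(log(pmax(p[cbind(y[idx], seq_along(idx))], 1e-12)))
      model$bwd((p - onehot[, idx, drop = FALSE]) / length(idx))
      opt$step()
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = total / n))
    if (verbose) message(sprintf("epoch %d  loss %.4f", epoch, total / n))
  }
  refresh_bn_stats(model, function() model$fwd(x_all, training = TRUE))
  model$history <- history
  model
}

#' Fall probabilities from a trained audio model
#'
#' @param model A trained `mobilenet_model`.
#' @param images As in [train_audio_model()].
#' @return Numeric vector of fall probabilities.
#' @export
predict_audio <- function(model, images) {
  mobilenet_forward(model, images)[, "fall"]
}
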