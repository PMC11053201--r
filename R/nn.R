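# Minimal neural-network core: layer objects with explicit forward/backward
# passes over column-major arrays, plus an Adam optimizer. Layers are
# environments so parameters and gradients can be updated in place. Shared by
# the skeleton (ST-GCN) and audio (MobileNetV2) branches.
#
# Array layouts (channels first, trailing batch):
#   spatio-temporal features: [C, T, V, N]  (channels, frames, joints, batch)
#   images:                   [C, H, W, N]

new_layer <- function(type, init = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$param_names <- character(0)
  for (nm in names(init)) assign(nm, init[[nm]], envir = e)
  e
}

# He/Kaiming-style initialization: suits ReLU nonlinearities.
init_weight <- function(n_out, n_in_eff, shape) {
  array(stats::rnorm(prod(shape), sd = sqrt(2 / n_in_eff)), dim = shape)
}

flatc <- function(x) {                              # [C, ...] -> C x M
  dim(x) <- c(dim(x)[1], length(x) %/% dim(x)[1])
  x
}

## ---- elementwise layers -------------------------------------------------

nn_relu <- function(max_val = Inf) {
  e <- new_layer("relu")
  e$max_val <- max_val
  e$fwd <- function(x, training = TRUE) {
    y <- pmin(pmax(x, 0), e$max_val)
    e$mask <- (x > 0) & (x < e$max_val)
    y
  }
  e$bwd <- function(dy) dy * e$mask
  e
}

nn_dropout <- function(rate = 0.5) {
  e <- new_layer("dropout")
  e$rate <- rate
  e$fwd <- function(x, training = TRUE) {
    if (!training || e$rate <= 0) {
      e$mask <- NULL
      return(x)
    }
    keep <- 1 - e$rate
    e$mask <- array(stats::runif(length(x)) < keep, dim = dim(x)) / keep
    x * e$mask
  }
  e$bwd <- function(dy) if (is.null(e$mask)) dy else dy * e$mask
  e
}

## ---- batch normalization (per leading channel) --------------------------

nn_batchnorm <- function(channels, momentum = 0.1, eps = 1e-5) {
  e <- new_layer("batchnorm")
  e$gamma <- rep(1, channels)
  e$beta <- rep(0, channels)
  e$param_names <- c("gamma", "beta")
  e$run_mean <- rep(0, channels)
  e$run_var <- rep(1, channels)
  e$momentum <- momentum
  e$eps <- eps
  e$fwd <- function(x, training = TRUE) {
    xm <- flatc(x)
    if (training) {
      mu <- rowMeans(xm)
      v <- rowMeans(xm^2) - mu^2
      e$run_mean <- (1 - e$momentum) * e$run_mean + e$momentum * mu
      e$run_var <- (1 - e$momentum) * e$run_var + e$momentum * v
    } else {
      mu <- e$run_mean
      v <- e$run_var
    }
    inv <- 1 / sqrt(v + e$eps)
    xhat <- (xm - mu) * inv
    e$cache <- list(xhat = xhat, inv = inv, dims = dim(x), training = training)
    array(e$gamma * xhat + e$beta, dim = dim(x))
  }
  e$bwd <- function(dy) {
    cc <- e$cache
    dym <- flatc(dy)
    e$dgamma <- rowSums(dym * cc$xhat)
    e$dbeta <- rowSums(dym)
    if (!cc$training) {
      return(array(e$gamma * cc$inv * dym, dim = cc$dims))
    }
    M <- ncol(dym)
    dx <- (e$gamma * cc$inv / M) *
      (M * dym - e$dbeta - cc$xhat * e$dgamma)
    array(dx, dim = cc$dims)
  }
  e
}

## ---- 1x1 channel map (pointwise linear over channels) -------------------

nn_pointwise <- function(in_ch, out_ch, bias = TRUE) {
  e <- new_layer("pointwise")
  e$W <- init_weight(out_ch, in_ch, c(out_ch, in_ch))
  e$param_names <- "W"
  if (bias) {
    e$b <- rep(0, out_ch)
    e$param_names <- c("W", "b")
  }
  e$fwd <- function(x, training = TRUE) {
    e$x <- x
    y <- e$W %*% flatc(x)
    if (!is.null(e$b)) y <- y + e$b
    array(y, dim = c(nrow(e$W), dim(x)[-1]))
  }
  e$bwd <- function(dy) {
    dym <- flatc(dy)
    e$dW <- tcrossprod(dym, flatc(e$x))
    if (!is.null(e$b)) e$db <- rowSums(dym)
    array(crossprod(e$W, dym), dim = dim(e$x))
  }
  e
}

## ---- temporal convolution over [C, T, V, N] ------------------------------

# Zero-pad dimension 2 (time) by p on both sides.
pad_time <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2] + 2 * p, d[3], d[4]))
  out[, (p + 1):(p + d[2]), , ] <- x
  out
}

nn_temporal_conv <- function(in_ch, out_ch, kernel = 9, stride = 1) {
  if (kernel %% 2 != 1) stop("temporal kernel must be odd")
  if (!stride %in% c(1, 2)) stop("temporal stride must be 1 or 2")
  e <- new_layer("tconv")
  e$kernel <- kernel
  e$stride <- stride
  e$pad <- (kernel - 1) %/% 2
  e$W <- init_weight(out_ch, in_ch * kernel, c(out_ch, in_ch * kernel))
  e$b <- rep(0, out_ch)
  e$param_names <- c("W", "b")
  e$fwd <- function(x, training = TRUE) {
    d <- dim(x)
    xp <- pad_time(x, e$pad)
    t_out <- (d[2] + 2 * e$pad - e$kernel) %/% e$stride + 1
    cols <- vector("list", e$kernel)
    for (k in seq_len(e$kernel)) {
      idx <- k + e$stride * (seq_len(t_out) - 1)
      cols[[k]] <- flatc(xp[, idx, , , drop = FALSE])       # C_in x (t_out*V*N)
    }
    xc <- do.call(rbind, cols)                              # (C_in*K) x M
    e$cache <- list(xc = xc, dims = d, t_out = t_out)
    array(e$W %*% xc + e$b, dim = c(nrow(e$W), t_out, d[3], d[4]))
  }
  e$bwd <- function(dy) {
    cc <- e$cache
    dym <- flatc(dy)
    e$dW <- tcrossprod(dym, cc$xc)
    e$db <- rowSums(dym)
    dxc <- crossprod(e$W, dym)
    d <- cc$dims
    in_ch <- d[1]
    dxp <- array(0, dim = c(in_ch, d[2] + 2 * e$pad, d[3], d[4]))
    for (k in seq_len(e$kernel)) {
      idx <- k + e$stride * (seq_len(cc$t_out) - 1)
      blk <- array(dxc[((k - 1) * in_ch + 1):(k * in_ch), ],
                   dim = c(in_ch, cc$t_out, d[3], d[4]))
      dxp[, idx, , ] <- dxp[, idx, , , drop = FALSE] + blk
    }
    dxp[, (e$pad + 1):(e$pad + d[2]), , , drop = FALSE]
  }
  e
}

## ---- spatial graph convolution over [C, T, V, N] -------------------------

# Apply a V x V matrix over the joint dimension.
apply_adj <- function(x, A) {
  d <- dim(x)
  m <- matrix(aperm(x, c(3, 1, 2, 4)), nrow = d[3])        # V x (C*T*N)
  y <- A %*% m
  aperm(array(y, dim = c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

# One weight block per adjacency partition: y = sum_p W_p (A_p x) + b.
nn_graph_conv <- function(in_ch, out_ch, adjacency) {
  e <- new_layer("gconv")
  e$A <- adjacency                                          # V x V x P
  P <- dim(adjacency)[3]
  e$W <- init_weight(out_ch, in_ch * P, c(out_ch, in_ch, P))
  e$b <- rep(0, out_ch)
  e$param_names <- c("W", "b")
  e$fwd <- function(x, training = TRUE) {
    d <- dim(x)
    e$xp <- vector("list", P)
    y <- 0
    for (p in seq_len(P)) {
      xp <- apply_adj(x, e$A[, , p])
      e$xp[[p]] <- xp
      y <- y + e$W[, , p] %*% flatc(xp)
    }
    e$dims <- d
    array(y + e$b, dim = c(dim(e$W)[1], d[2], d[3], d[4]))
  }
  e$bwd <- function(dy) {
    dym <- flatc(dy)
    e$dW <- array(0, dim = dim(e$W))
    e$db <- rowSums(dym)
    dx <- array(0, dim = e$dims)
    for (p in seq_len(dim(e$A)[3])) {
      e$dW[, , p] <- tcrossprod(dym, flatc(e$xp[[p]]))
      dxp <- array(crossprod(e$W[, , p], dym), dim = e$dims)
      dx <- dx + apply_adj(dxp, t(e$A[, , p]))
    }
    dx
  }
  e
}

## ---- 2-D convolution over [C, H, W, N] (with groups) ---------------------

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  out
}

nn_conv2d <- function(in_ch, out_ch, kernel = 3, stride = 1, pad = NULL,
                      groups = 1, bias = FALSE) {
  if (in_ch %% groups != 0 || out_ch %% groups != 0) {
    stop("channel counts must be divisible by groups")
  }
  e <- new_layer("conv2d")
  e$kernel <- kernel
  e$stride <- stride
  e$pad <- if (is.null(pad)) (kernel - 1) %/% 2 else pad
  e$groups <- groups
  icg <- in_ch %/% groups
  ocg <- out_ch %/% groups
  e$icg <- icg
  e$ocg <- ocg
  # one (ocg x icg*k*k) weight matrix per group
  e$W <- init_weight(ocg, icg * kernel * kernel,
                     c(ocg, icg * kernel * kernel, groups))
  e$param_names <- "W"
  if (bias) {
    e$b <- rep(0, out_ch)
    e$param_names <- c("W", "b")
  }
  e$fwd <- function(x, training = TRUE) {
    d <- dim(x)
    xp <- pad_hw(x, e$pad)
    h_out <- (d[2] + 2 * e$pad - e$kernel) %/% e$stride + 1
    w_out <- (d[3] + 2 * e$pad - e$kernel) %/% e$stride + 1
    hi <- e$stride * (seq_len(h_out) - 1)
    wi <- e$stride * (seq_len(w_out) - 1)
    e$cache <- list(dims = d, h_out = h_out, w_out = w_out, xc = vector("list", e$groups))
    y <- array(0, dim = c(e$ocg * e$groups, h_out, w_out, d[4]))
    for (g in seq_len(e$groups)) {
      ch <- ((g - 1) * e$icg + 1):(g * e$icg)
      cols <- vector("list", e$kernel * e$kernel)
      idx <- 1
      for (kj in seq_len(e$kernel)) for (ki in seq_len(e$kernel)) {
        cols[[idx]] <- flatc(xp[ch, hi + ki, wi + kj, , drop = FALSE])
        idx <- idx + 1
      }
      xc <- do.call(rbind, cols)                       # (icg*k*k) x (h*w*N)
      e$cache$xc[[g]] <- xc
      och <- ((g - 1) * e$ocg + 1):(g * e$ocg)
      Wg <- matrix(e$W[, , g], nrow = e$ocg)
      y[och, , , ] <- array(Wg %*% xc, dim = c(e$ocg, h_out, w_out, d[4]))
    }
    if (!is.null(e$b)) y <- y + e$b
    y
  }
  e$bwd <- function(dy) {
    cc <- e$cache
    d <- cc$dims
    if (!is.null(e$b)) e$db <- rowSums(flatc(dy))
    e$dW <- array(0, dim = dim(e$W))
    hp <- d[2] + 2 * e$pad
    wp <- d[3] + 2 * e$pad
    dxp <- array(0, dim = c(d[1], hp, wp, d[4]))
    hi <- e$stride * (seq_len(cc$h_out) - 1)
    wi <- e$stride * (seq_len(cc$w_out) - 1)
    for (g in seq_len(e$groups)) {
      ch <- ((g - 1) * e$icg + 1):(g * e$icg)
      och <- ((g - 1) * e$ocg + 1):(g * e$ocg)
      dym <- flatc(dy[och, , , , drop = FALSE])
      e$dW[, , g] <- tcrossprod(dym, cc$xc[[g]])
      Wg <- matrix(e$W[, , g], nrow = e$ocg)
      dxc <- crossprod(Wg, dym)                             # (icg*k*k) x M
      idx <- 1
      for (kj in seq_len(e$kernel)) for (ki in seq_len(e$kernel)) {
        rows <- ((idx - 1) * e$icg + 1):(idx * e$icg)
        blk <- array(dxc[rows, ], dim = c(e$icg, cc$h_out, cc$w_out, d[4]))
        dxp[ch, hi + ki, wi + kj, ] <-
          dxp[ch, hi + ki, wi + kj, , drop = FALSE] + blk
        idx <- idx + 1
      }
    }
    dxp[, (e$pad + 1):(e$pad + d[2]), (e$pad + 1):(e$pad + d[3]), , drop = FALSE]
  }
  e
}

## ---- pooling and head ----------------------------------------------------

# Global average over all non-channel, non-batch dimensions: [C, ..., N] -> C x N
nn_global_pool <- function() {
  e <- new_layer("gpool")
  e$fwd <- function(x, training = TRUE) {
    d <- dim(x)
    e$dims <- d
    nd <- length(d)
    m <- prod(d[-c(1, nd)])
    xm <- array(x, dim = c(d[1], m, d[nd]))
    apply(xm, c(1, 3), mean)                           # C x N
  }
  e$bwd <- function(dy) {
    d <- e$dims
    nd <- length(d)
    m <- prod(d[-c(1, nd)])
    dyn <- dy / m                                      # C x N
    out <- array(0, dim = c(d[1], m, d[nd]))
    for (n in seq_len(d[nd])) out[, , n] <- dyn[, n]
    array(out, dim = d)
  }
  e
}

nn_dense <- function(in_dim, out_dim) {
  e <- new_layer("dense")
  e$W <- init_weight(out_dim, in_dim, c(out_dim, in_dim))
  e$b <- rep(0, out_dim)
  e$param_names <- c("W", "b")
  e$fwd <- function(x, training = TRUE) {
    e$x <- x                                           # in_dim x N
    e$W %*% x + e$b
  }
  e$bwd <- function(dy) {
    e$dW <- tcrossprod(dy, e$x)
    e$db <- rowSums(dy)
    crossprod(e$W, dy)
  }
  e
}

## ---- sequential container ------------------------------------------------

nn_sequential <- function(...) {
  e <- new_layer("sequential")
  e$layers <- list(...)
  e$fwd <- function(x, training = TRUE) {
    for (l in e$layers) x <- l$fwd(x, training)
    x
  }
  e$bwd <- function(dy) {
    for (l in rev(e$layers)) dy <- l$bwd(dy)
    dy
  }
  e
}

# Depth-first collection of parameterized layer environments.
collect_layers <- function(layer) {
  if (layer$type == "sequential") {
    unlist(lapply(layer$layers, collect_layers), recursive = FALSE)
  } else if (!is.null(layer$sublayers)) {
    unlist(lapply(layer$sublayers, collect_layers), recursive = FALSE)
  } else {
    list(layer)
  }
}

n_parameters <- function(net) {
  ls <- collect_layers(net)
  sum(vapply(ls, function(l) {
    sum(vapply(l$param_names, function(nm) length(get(nm, envir = l)), numeric(1)))
  }, numeric(1)))
}

## ---- Adam optimizer -------------------------------------------------------

adam_optimizer <- function(net, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8, weight_decay = 0) {
  layers <- collect_layers(net)
  state <- lapply(layers, function(l) {
    s <- list()
    for (nm in l$param_names) {
      p <- get(nm, envir = l)
      s[[nm]] <- list(m = p * 0, v = p * 0)    # zeros, same structure as p
    }
    s
  })
  t_step <- 0
  step <- function() {
    t_step <<- t_step + 1
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      for (nm in l$param_names) {
        g <- get(paste0("d", nm), envir = l)
        p <- get(nm, envir = l)
        if (weight_decay > 0 && nm %in% c("W", "gamma")) g <- g + weight_decay * p
        st <- state[[i]][[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        state[[i]][[nm]] <<- st
        mhat <- st$m / (1 - beta1^t_step)
        vhat <- st$v / (1 - beta2^t_step)
        assign(nm, p - lr * mhat / (sqrt(vhat) + eps), envir = l)
      }
    }
  }
  list(step = step, layers = layers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Re-estimate batch-norm running statistics after training: one forward pass
# over the training set with dropout disabled and momentum 1, so inference
# normalizes with statistics that match the final weights (the few momentum
# updates made during a short training run lag behind them).
refresh_bn_stats <- function(net, forward_call) {
  layers <- collect_layers(net)
  bns <- Filter(function(l) l$type == "batchnorm", layers)
  drops <- Filter(function(l) l$type == "dropout", layers)
  old_m <- lapply(bns, function(l) l$momentum)
  old_r <- lapply(drops, function(l) l$rate)
  for (l in bns) l$momentum <- 1
  for (l in drops) l$rate <- 0
  on.exit({
    for (i in seq_along(bns)) bns[[i]]$momentum <- old_m[[i]]
    for (i in seq_along(drops)) drops[[i]]$rate <- old_r[[i]]
  })
  forward_call()
  invisible(NULL)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood for binary labels:
#' `-(1/N) * sum(y*log(p) + (1-y)*log(1-p))`, with predictions clipped to
#' `(eps, 1-eps)` for numerical safety.
#'
#' @param y_true Vector of labels in `{0, 1}` (1 = fall).
#' @param y_pred Vector of predicted probabilities in `[0, 1]`.
#' @param eps Clipping constant, default `1e-7`.
#' @return Non-negative scalar loss.
#' @examples
#' bce_loss(c(1, 0), c(0.5, 0.5)) # log(2)
#' @export
bce_loss <- function(y_true, y_pred, eps = 1e-7) {
  if (length(y_true) == 0) stop("empty batch")
  if (length(y_true) != length(y_pred)) stop("label/prediction length mismatch")
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0 or 1")
  check_prob(y_pred, "y_pred")
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}
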