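# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results from first principles (explicit
# sums, exhaustive scans) rather than calling the implementation paths they
# check.

# Brute-force spatial graph convolution: for each frame and node, sum over
# the 1-hop neighborhood with neighborhood-size normalization and one weight
# matrix per partition subset. Partition labels are recomputed here from the
# raw adjacency and hop distances, independently of the package's adjacency
# stacks.
oracle_graph_conv <- function(features, A, strategy, weights, center = 1) {
  n <- nrow(A)
  d <- dim(features)
  out <- array(0, dim = c(d[1], n, ncol(weights[[1]])))
  # hop distances by BFS
  hop <- matrix(Inf, n, n)
  diag(hop) <- 0
  for (k in 1:n) {
    prev <- hop
    for (i in 1:n) for (j in 1:n) if (A[i, j] == 1) {
      hop[i, ] <- pmin(hop[i, ], prev[j, ] + 1)
    }
  }
  subset_of <- function(i, j) {
    if (strategy == "uni-label") return(1L)
    if (strategy == "distance") return(if (i == j) 1L else 2L)
    r_i <- hop[i, center]; r_j <- hop[j, center]
    if (i == j || r_j == r_i) 1L else if (r_j < r_i) 2L else 3L
  }
  for (t in seq_len(d[1])) {
    for (i in seq_len(n)) {
      nbr <- which(A[i, ] == 1 | seq_len(n) == i)    # B(v) = self + 1-hop
      Z <- length(nbr)
      for (j in nbr) {
        w <- weights[[subset_of(i, j)]]
        out[t, i, ] <- out[t, i, ] + (features[t, j, ] %*% w) / Z
      }
    }
  }
  out
}

# Exhaustive Dempster combination on {fall, notfall, theta}: enumerate all
# nine product terms and route them by set intersection.
oracle_dempster <- function(m1, m2) {
  sets <- list(fall = "f", notfall = "n", theta = c("f", "n"))
  out <- c(fall = 0, notfall = 0, theta = 0)
  K <- 0
  for (a in names(sets)) for (b in names(sets)) {
    inter <- intersect(sets[[a]], sets[[b]])
    prod <- m1[[a]] * m2[[b]]
    if (length(inter) == 0) {
      K <- K + prod
    } else if (setequal(inter, c("f", "n"))) {
      out["theta"] <- out["theta"] + prod
    } else if (identical(inter, "f")) {
      out["fall"] <- out["fall"] + prod
    } else {
      out["notfall"] <- out["notfall"] + prod
    }
  }
  list(mass = out / (1 - K), K = K)
}

# Exhaustive consecutive-run scan: label fall iff any window of run_length
# consecutive frames is all above threshold; fall confidence = max mean over
# maximal qualifying runs.
oracle_aggregate <- function(prob, run_length, threshold = 0.5) {
  T_ <- length(prob)
  is_fall <- prob > threshold
  any_run <- FALSE
  for (s in seq_len(T_ - run_length + 1)) {
    if (all(is_fall[s:(s + run_length - 1)])) any_run <- TRUE
  }
  if (!any_run) return(list(label = "notfall"))
  # maximal runs
  best <- -Inf
  s <- 1
  while (s <= T_) {
    if (is_fall[s]) {
      e <- s
      while (e < T_ && is_fall[e + 1]) e <- e + 1
      if (e - s + 1 >= run_length) best <- max(best, mean(prob[s:e]))
      s <- e + 1
    } else s <- s + 1
  }
  list(label = "fall", confidence = best)
}

# Tiny deterministic skeleton sequence: standing pose plus optional motion.
toy_sequence <- function(T_ = 20, jitter = 0, seed = 1, label = "notfall") {
  set.seed(seed)
  base <- cbind(
    x = c(160, 156, 164, 152, 168, 146, 174, 142, 178, 140, 180,
          151, 169, 150, 170, 149, 171),
    y = c(68, 64, 64, 67, 67, 85, 85, 108, 108, 130, 130,
          140, 140, 172, 172, 202, 202)
  )
  kp <- array(0, dim = c(T_, 17, 3))
  for (t in seq_len(T_)) {
    kp[t, , 1:2] <- base + matrix(stats::rnorm(34, sd = jitter), 17, 2)
    kp[t, , 3] <- 0.9
  }
  skeleton_sequence(kp, clip_id = paste0("toy", seed), label = label)
}

# Short synthetic audio clip (sine plus noise) for augmentation/IO tests.
toy_clip <- function(duration = 0.5, sr = 8000, seed = 1, label = "notfall") {
  set.seed(seed)
  t <- seq(0, duration, length.out = round(duration * sr))
  audio_clip(0.3 * sin(2 * pi * 440 * t) + 0.01 * stats::rnorm(length(t)),
             sr, paste0("toyclip", seed), label)
}
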