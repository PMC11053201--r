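# Audio preprocessing, augmentation, log-mel feature extraction and k-fold
# evaluation for the audio branch of the fall detector.

#' Energy-gated silence trimming
#'
#' Automated replacement for manual removal of irrelevant quiet segments:
#' leading and trailing regions whose short-time RMS falls below
#' `threshold_db` relative to the clip's peak RMS are removed, keeping
#' `pad_ms` of context on each side. A clip that is quiet throughout (nothing
#' above the gate) is returned unchanged with attribute `"all_silent" = TRUE`
#' and a warning.
#'
#' @param clip An `audio_clip`.
#' @param threshold_db Gate level in dB relative to peak RMS, default -40.
#' @param pad_ms Context retained around the active region, default 50 ms.
#' @param frame_length RMS window in samples, default 1024.
#' @return The trimmed `audio_clip` (never empty).
#' @export
energy_gate_trim <- function(clip, threshold_db = -40, pad_ms = 50,
                             frame_length = 1024) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  n <- length(x)
  hop <- max(1L, frame_length %/% 4L)
  starts <- seq(1L, max(1L, n - frame_length + 1L), by = hop)
  rms <- vapply(starts, function(s) {
    seg <- x[s:min(s + frame_length - 1L, n)]
    sqrt(mean(seg^2))
  }, numeric(1))
  peak <- max(rms)
  if (peak == 0) {
    warning("clip '", clip$clip_id, "' is pure silence; returned unchanged")
    attr(clip, "all_silent") <- TRUE
    return(clip)
  }
  active <- rms > peak * 10^(threshold_db / 20)
  if (!any(active)) {
    warning("clip '", clip$clip_id, "' has no frames above the energy gate")
    attr(clip, "all_silent") <- TRUE
    return(clip)
  }
  pad <- round(pad_ms / 1000 * clip$sample_rate)
  first <- max(1L, starts[which(active)[1]] - pad)
  last_frame <- which(active)[sum(active)]
  last <- min(n, starts[last_frame] + frame_length - 1L + pad)
  out <- audio_clip(x[first:last], clip$sample_rate, clip$clip_id, clip$label)
  attr(out, "trim_bounds") <- c(first, last)
  out
}

#' Audio augmentation
#'
#' One of five label-preserving transformations used to expand the training
#' corpus: `white_noise` adds Gaussian noise at `snr_db` below the signal
#' power; `stretch_longer`/`stretch_shorter` resample the time axis by
#' `stretch_factor` (default 1.2) / its reciprocal regime (default 0.8),
#' lengthening or shortening the clip; `volume_up`/`volume_down` apply
#' `gain_db` (default +6 / -6 dB). Gains are applied without hard clipping so
#' opposite gains invert exactly.
#'
#' @param clip An `audio_clip`.
#' @param method One of `"white_noise"`, `"stretch_longer"`,
#'   `"stretch_shorter"`, `"volume_up"`, `"volume_down"`.
#' @param seed RNG seed for the noise method (required for reproducibility).
#' @param snr_db Signal-to-noise ratio for `white_noise`, default 20 dB.
#' @param stretch_factor Duration factor, default 1.2 (longer) / 0.8 (shorter).
#' @param gain_db Gain magnitude in dB, default 6.
#' @return The augmented `audio_clip`, `clip_id` suffixed with the method.
#' @export
augment <- function(clip, method = c("white_noise", "stretch_longer",
                                     "stretch_shorter", "volume_up", "volume_down"),
                    seed = NULL, snr_db = 20, stretch_factor = NULL, gain_db = 6) {
  stopifnot(inherits(clip, "audio_clip"))
  method <- match.arg(method)
  x <- clip$samples
  y <- switch(method,
    white_noise = {
      if (!is.null(seed)) set.seed(seed)
      sig_pow <- mean(x^2)
      noise_sd <- sqrt(sig_pow / 10^(snr_db / 10))
      x + stats::rnorm(length(x), sd = noise_sd)
    },
    stretch_longer = resample_time(x, stretch_factor %||% 1.2),
    stretch_shorter = resample_time(x, stretch_factor %||% 0.8),
    volume_up = x * 10^(gain_db / 20),
    volume_down = x * 10^(-gain_db / 20)
  )
  audio_clip(y, clip$sample_rate, paste(clip$clip_id, method, sep = "_"),
             clip$label)
}

# Linear-interpolation playback-speed change: factor > 1 lengthens.
resample_time <- function(x, factor) {
  n_out <- max(2L, round(length(x) * factor))
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out))$y
}

#' Expand a clip set with all augmentation methods
#'
#' Every clip yields itself plus one clip per enabled method: with all five
#' methods the corpus grows by a factor of exactly 6 (e.g. 260 clips become
#' 1560).
#'
#' @param clips List of `audio_clip`s.
#' @param methods Augmentation methods to apply; default all five.
#' @param seed Base seed; clip `i` uses `seed + i` for its noise draw.
#' @return List of originals followed by augmented clips.
#' @export
expand_dataset <- function(clips, methods = c("white_noise", "stretch_longer",
                                              "stretch_shorter", "volume_up",
                                              "volume_down"), seed = 1L) {
  aug <- list()
  for (i in seq_along(clips)) {
    for (m in methods) {
      aug[[length(aug) + 1L]] <- augment(clips[[i]], m, seed = seed + i)
    }
  }
  c(clips, aug)
}

#' Log-scaled mel spectrogram
#'
#' Short-time Fourier magnitude-squared spectra on a Hann window, projected
#' onto a triangular mel filterbank and log10-compressed with floor `eps`.
#' Frame count with centering off is `1 + floor((L - n_fft)/hop)`.
#'
#' @param clip An `audio_clip` at least `n_fft` samples long.
#' @param n_fft FFT window length, default 1024.
#' @param hop Hop length in samples, default 512.
#' @param n_mels Number of mel bands, default 64.
#' @param fmin,fmax Filterbank frequency range in Hz; default 0 to Nyquist.
#' @param eps Power floor before the log, default 1e-10.
#' @return A `mel_spectrogram`: list with `matrix` (`n_mels` x frames of
#'   log10-power), and `params`.
#' @export
logmel <- function(clip, n_fft = 1024, hop = 512, n_mels = 64,
                   fmin = 0, fmax = NULL, eps = 1e-10) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  if (length(x) < n_fft) {
    stop("clip (", length(x), " samples) shorter than one FFT window (", n_fft, ")")
  }
  sr <- clip$sample_rate
  fmax <- fmax %||% (sr / 2)
  n_frames <- 1L + (length(x) - n_fft) %/% hop
  win <- as.numeric(signal::hanning(n_fft))
  n_bins <- n_fft %/% 2L + 1L
  power <- matrix(0, n_bins, n_frames)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1L) * hop + 1L):((f - 1L) * hop + n_fft)] * win
    sp <- stats::fft(seg)[seq_len(n_bins)]
    power[, f] <- Re(sp)^2 + Im(sp)^2
  }
  fb <- mel_filterbank(n_mels, n_fft, sr, fmin, fmax)
  mel_power <- fb %*% power
  structure(list(matrix = log10(pmax(mel_power, eps)),
                 params = list(n_fft = n_fft, hop = hop, n_mels = n_mels,
                               sample_rate = sr, fmin = fmin, fmax = fmax,
                               eps = eps)),
            class = "mel_spectrogram")
}

# Triangular mel filterbank (HTK mel scale), n_mels x (n_fft/2 + 1).
mel_filterbank <- function(n_mels, n_fft, sr, fmin, fmax) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  n_bins <- n_fft %/% 2L + 1L
  bin_freq <- (seq_len(n_bins) - 1) * sr / n_fft
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; mid <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_freq - lo) / (mid - lo)
    down <- (hi - bin_freq) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' @export
print.mel_spectrogram <- function(x, ...) {
  cat(sprintf("Log-mel spectrogram: %d mel bands x %d frames (n_fft %d, hop %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$params$n_fft, x$params$hop))
  invisible(x)
}

#' Resize a mel spectrogram to the classifier's square input image
#'
#' Bilinear resize to `size` x `size`, then a fixed affine rescaling of the
#' log-power axis so the floor maps to -1 and 0 (unit power) to +1. The
#' normalization is deliberately global rather than per-image: absolute level
#' carries class information (an impact is loud), and a per-image standard
#' score would make soft transients indistinguishable from loud ones.
#'
#' @param spec A `mel_spectrogram`.
#' @param size Side length of the square input, default 224.
#' @param center,scale Affine normalization `(x - center)/scale`; defaults
#'   derived from the spectrogram's log floor (`log10(eps)/2` and
#'   `|log10(eps)|/2`).
#' @return `size` x `size` numeric matrix.
#' @export
mel_to_image <- function(spec, size = 224, center = NULL, scale = NULL) {
  stopifnot(inherits(spec, "mel_spectrogram"))
  floor_log <- log10(spec$params$eps)
  center <- center %||% (floor_log / 2)
  scale <- scale %||% abs(floor_log / 2)
  img <- EBImage::resize(EBImage::Image(spec$matrix), w = size, h = size)
  (EBImage::imageData(img) - center) / scale
}

#' Stratified k-fold cross-validation
#'
#' Splits samples into `k` stratified folds (each sample tested exactly once,
#' fold sizes differing by at most one per class), trains with `train_fn` on
#' the complement and scores the held-out fold with `predict_fn`, reporting
#' the five classification metrics per fold and their averages.
#'
#' @param x List (or indexable collection) of inputs.
#' @param labels Character labels (`"fall"`/`"notfall"`) aligned with `x`.
#' @param k Number of folds, default 5.
#' @param seed Seed for the fold shuffle.
#' @param train_fn `function(x_train, labels_train)` returning a model.
#' @param predict_fn `function(model, x_test)` returning fall probabilities.
#' @param threshold Decision threshold on the predicted probability.
#' @return A `cv_report`: list with `folds` (data frame of per-fold metrics),
#'   `average` (named means), `k`, and `assignments`.
#' @export
kfold_evaluate <- function(x, labels, k = 5, seed = 1L, train_fn, predict_fn,
                           threshold = 0.5) {
  n <- length(x)
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  labels <- as_fall_label(labels)
  if (length(labels) != n) stop("labels must align with x")
  fold <- stratified_folds(labels, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (length(unique(labels[tr])) < 2 || length(te) == 0) {
      stop("fold ", f, " lacks both classes; use fewer folds or more data")
    }
    model <- train_fn(x[tr], labels[tr])
    p <- predict_fn(model, x[te])
    pred <- ifelse(p > threshold, "fall", "notfall")
    m <- metrics(confusion(pred, labels[te]))
    data.frame(fold = f, sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy = m$accuracy, precision = m$precision, f1 = m$f1)
  })
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 average = colMeans(folds[, -1, drop = FALSE], na.rm = TRUE),
                 k = k, assignments = fold),
            class = "cv_report")
}

# Stratified fold ids: within each class, shuffled samples are dealt
# round-robin so fold sizes differ by at most 1 per class.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (percentages):\n", x$k))
  df <- x$folds
  df[, -1] <- round(df[, -1], 2)
  print(df, row.names = FALSE)
  cat("Average:", paste(sprintf("%s %.2f%%", names(x$average), x$average),
                        collapse = "  "), "\n")
  invisible(x)
}
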