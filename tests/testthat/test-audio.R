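test_that("WAV files round-trip through the reader and writer", {
  clip <- toy_clip(duration = 0.3, seed = 5)
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, p16, bits = 16)
  back16 <- read_wav(p16)
  expect_equal(back16$sample_rate, clip$sample_rate)
  expect_lt(max(abs(back16$samples - clip$samples)), 1 / 32000)
  p32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, p32, bits = 32)
  back32 <- read_wav(p32)
  expect_equal(back32$samples, clip$samples, tolerance = 1e-7)
  expect_error(read_wav(withr::local_tempfile(fileext = ".wav")), "not found")
})

test_that("the energy gate trims silence but never empties a clip", {
  sr <- 8000
  # silence - burst - silence
  burst <- 0.5 * sin(2 * pi * 500 * seq(0, 0.4, length.out = 0.4 * sr))
  x <- c(rep(0, sr), burst, rep(0, sr))
  clip <- audio_clip(x, sr, "sbs")
  trimmed <- energy_gate_trim(clip, pad_ms = 50)
  bounds <- attr(trimmed, "trim_bounds")
  expect_lt(length(trimmed$samples), length(x))
  expect_true(bounds[1] <= sr + 1 && bounds[1] > sr - 0.2 * sr)
  expect_gte(max(abs(trimmed$samples)), 0.45)     # burst retained
  # pure silence returns unchanged with a flag
  expect_warning(still <- energy_gate_trim(audio_clip(rep(0, sr), sr)), "silence")
  expect_true(attr(still, "all_silent"))
  expect_equal(length(still$samples), sr)
  # an already-trimmed clip is (nearly) a fixed point
  again <- energy_gate_trim(trimmed, pad_ms = 50)
  expect_gte(length(again$samples), length(trimmed$samples) - 800)
})

test_that("augmentations preserve labels and invert or reproduce exactly", {
  clip <- toy_clip(seed = 9, label = "fall")
  up <- augment(clip, "volume_up")
  down <- augment(up, "volume_down")
  expect_equal(down$samples, clip$samples, tolerance = 1e-6)
  expect_equal(up$label, "fall")
  n1 <- augment(clip, "white_noise", seed = 4)
  n2 <- augment(clip, "white_noise", seed = 4)
  expect_identical(n1$samples, n2$samples)
  expect_false(identical(n1$samples, augment(clip, "white_noise", seed = 5)$samples))
  # stretch factors change the length as specified
  expect_equal(length(augment(clip, "stretch_longer")$samples),
               round(length(clip$samples) * 1.2))
  expect_equal(length(augment(clip, "stretch_shorter")$samples),
               round(length(clip$samples) * 0.8))
  expect_error(augment(clip, "reverse"))
})

test_that("expanding with all five methods multiplies the corpus by six", {
  clips <- lapply(1:20, function(i) toy_clip(duration = 0.1, seed = i,
                                             label = if (i %% 2) "fall" else "notfall"))
  out <- expand_dataset(clips)
  expect_length(out, 120)
  labs <- vapply(clips, function(c) c$label, character(1))
  # originals first, then the five augmented variants of each clip in order
  expect_equal(vapply(out, function(c) c$label, character(1)),
               c(labs, rep(labs, each = 5)))
})

test_that("log-mel spectrograms obey the frame-count and scaling laws", {
  sr <- 8000
  L <- 1024 + 20 * 256
  set.seed(6)
  clip <- audio_clip(0.2 * rnorm(L), sr)
  sp <- logmel(clip, n_fft = 1024, hop = 256, n_mels = 32)
  expect_equal(dim(sp$matrix), c(32, 1 + (L - 1024) %/% 256))
  # silence sits at the log floor
  silence <- logmel(audio_clip(rep(0, 4096), sr), n_fft = 1024, hop = 256,
                    n_mels = 32)
  expect_true(all(silence$matrix == -10))
  # gain g shifts every (unfloored) value by 2 log10 g
  louder <- logmel(audio_clip(clip$samples * 3, sr), n_fft = 1024, hop = 256,
                   n_mels = 32)
  shift <- louder$matrix - sp$matrix
  expect_equal(mean(shift[sp$matrix > -9]), 2 * log10(3), tolerance = 1e-6)
  # appended silence shorter than the hop remainder leaves frames unchanged
  padded <- logmel(audio_clip(c(clip$samples, rep(0, 255)), sr),
                   n_fft = 1024, hop = 256, n_mels = 32)
  expect_equal(padded$matrix, sp$matrix)
  expect_error(logmel(audio_clip(rep(0.1, 100), sr), n_fft = 1024), "shorter")
})

test_that("spectrogram images resize to a fixed absolute scale", {
  clip <- toy_clip(duration = 0.5, seed = 2)
  sp <- logmel(clip, n_fft = 512, hop = 256, n_mels = 32)
  img <- mel_to_image(sp, size = 48)
  expect_equal(dim(img), c(48, 48))
  expect_true(all(img >= -1.01))
  # the floor maps to -1 regardless of content
  floor_img <- mel_to_image(logmel(audio_clip(rep(0, 4096), clip$sample_rate),
                                   n_fft = 512, hop = 256, n_mels = 32),
                            size = 48)
  expect_equal(as.numeric(floor_img), rep(-1, 48 * 48), tolerance = 1e-9)
})

test_that("stratified k-fold partitions and scores every sample once", {
  set.seed(44)
  n <- 37
  x <- as.list(rnorm(n, mean = rep(c(2, -2), length.out = n), sd = 0.3))
  labels <- rep(c("fall", "notfall"), length.out = n)
  # trivial threshold classifier stands in for the CNN to test the mechanics
  train_fn <- function(x_tr, y_tr) {
    mean(unlist(x_tr[y_tr == "fall"])) / 2 + mean(unlist(x_tr[y_tr == "notfall"])) / 2
  }
  predict_fn <- function(thresh, x_te) {
    as.numeric(unlist(x_te) > thresh)
  }
  rep5 <- kfold_evaluate(x, labels, k = 5, seed = 2, train_fn, predict_fn)
  expect_equal(sort(unique(rep5$assignments)), 1:5)
  expect_equal(length(rep5$assignments), n)
  # each sample in exactly one fold; fold sizes differ by at most 1 per class
  for (cl in c("fall", "notfall")) {
    sizes <- table(rep5$assignments[labels == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_equal(nrow(rep5$folds), 5)
  expect_named(rep5$average,
               c("sensitivity", "specificity", "accuracy", "precision", "f1"))
  expect_equal(unname(rep5$average[["accuracy"]]), 100)
  expect_error(kfold_evaluate(x[1:3], labels[1:3], k = 5, seed = 1,
                              train_fn, predict_fn), "exceeds")
})
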