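# Audio clip container and minimal RIFF/WAVE I/O (16-bit PCM and 32-bit
# float, mono). Written in-package: the installed R stack has no WAV reader.

#' Construct an audio clip
#'
#' @param samples Numeric waveform, nominally in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz, `> 0`.
#' @param clip_id Identifier.
#' @param label `"fall"`, `"notfall"`, or `NA`.
#' @return An `audio_clip` object (list with the above fields and `duration`
#'   in seconds).
#' @export
audio_clip <- function(samples, sample_rate = 16000, clip_id = "clip",
                       label = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty waveform")
  if (any(!is.finite(samples))) stop("waveform contains non-finite samples")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (!is.na(label)) label <- as_fall_label(label)
  structure(list(samples = samples, sample_rate = sample_rate,
                 clip_id = clip_id, label = label,
                 duration = length(samples) / sample_rate),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("Audio clip '%s': %.3f s @ %d Hz, label %s\n", x$clip_id,
              x$duration, x$sample_rate, ifelse(is.na(x$label), "unknown", x$label)))
  invisible(x)
}

#' Read a mono WAV file
#'
#' Supports uncompressed 16-bit PCM and 32-bit IEEE float, single channel.
#'
#' @param path WAV file path.
#' @inheritParams audio_clip
#' @return An `audio_clip`.
#' @export
read_wav <- function(path, clip_id = NULL, label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(clip_id)) clip_id <- sub("\\.[^.]+$", "", basename(path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop(path, " is not a RIFF file")
  readBin(con, integer(), 1, size = 4, endian = "little")   # chunk size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop(path, " is not a WAVE file")
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, integer(), 1, size = 2, endian = "little"),
        channels = readBin(con, integer(), 1, size = 2, endian = "little"),
        sample_rate = readBin(con, integer(), 1, size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), 1, size = 4, endian = "little"),
        block_align = readBin(con, integer(), 1, size = 2, endian = "little"),
        bits = readBin(con, integer(), 1, size = 2, endian = "little")
      )
      if (sz > 16) readBin(con, raw(), sz - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$channels != 1) stop("only mono WAV supported; got ", fmt$channels,
                                  " channels")
      n <- sz %/% (fmt$bits %/% 8)
      samples <- if (fmt$audio_format == 1 && fmt$bits == 16) {
        readBin(con, integer(), n, size = 2, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$audio_format == 3 && fmt$bits == 32) {
        readBin(con, numeric(), n, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$audio_format,
             ", ", fmt$bits, " bit)")
      }
      return(audio_clip(samples, fmt$sample_rate, clip_id, label))
    } else {
      readBin(con, raw(), sz + sz %% 2)                     # skip padded chunk
    }
  }
}

#' Write a mono WAV file
#'
#' @param clip An `audio_clip`.
#' @param path Output path.
#' @param bits 16 (PCM, samples clipped to `[-1, 1]`) or 32 (IEEE float).
#' @export
write_wav <- function(clip, path, bits = 16) {
  stopifnot(inherits(clip, "audio_clip"), bits %in% c(16, 32))
  n <- length(clip$samples)
  bytes_per <- bits %/% 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(clip$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    s <- pmin(pmax(clip$samples, -1), 1)
    writeBin(as.integer(round(s * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(clip$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}
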