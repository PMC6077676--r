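## Minimal RIFF/WAVE reader and writer for single-channel recordings.
## Supports 16-bit integer PCM (format 1) and 32-bit IEEE float (format 3),
## which covers the heart-sound databases this package targets.

#' Read a single-channel WAV file as a PCG recording
#'
#' Reads PCM16 or float32 WAV, scales integer samples to \[-1, 1\], and (by
#' default) resamples to the 2000 Hz working rate used throughout the
#' pipeline, via the polyphase resampler in \pkg{signal}.
#'
#' @param path Path to the WAV file.
#' @param rate Target sampling rate in Hz, or `NULL` to keep the file's rate.
#'   2000 Hz keeps the Nyquist frequency above the 820 Hz upper edge of the
#'   feature bands.
#' @param record_id Identifier; defaults to the file name without extension.
#' @return A [pcg_recording].
#' @export
read_wav <- function(path, rate = 2000, record_id = NULL) {
  if (!file.exists(path)) stop("WAV file does not exist: ", path)
  if (file.size(path) < 44) stop("not a valid WAV file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels = readBin(raw_fmt[3:4], "integer", 1, size = 2,
                             endian = "little", signed = FALSE),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV (data before fmt): ", path)
      if (fmt$audio_format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", size / 2, size = 2,
                           endian = "little") / 32767
      } else if (fmt$audio_format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "double", size / 4, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
             fmt$bits, " bit): ", path)
      }
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in WAV file: ", path)
  if (fmt$n_channels != 1) {
    stop("multi-channel WAV not supported (", fmt$n_channels,
         " channels): ", path)
  }

  fs <- fmt$sample_rate
  if (!is.null(rate) && rate != fs) {
    g <- gcd_int(round(rate), round(fs))
    samples <- signal::resample(samples, round(rate) / g, round(fs) / g)
    fs <- rate
  }
  id <- record_id %||% sub("\\.[^.]*$", "", basename(path))
  pcg_recording(samples, fs, record_id = id)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Write a PCG recording to a WAV file
#'
#' @param recording A [pcg_recording] (or numeric vector with `rate` given).
#' @param path Output path.
#' @param bit_depth `"float32"` (lossless for this pipeline) or `"pcm16"`
#'   (16-bit integer; samples are expected in \[-1, 1\] and are clipped).
#' @param rate Sampling rate, only needed when `recording` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path, bit_depth = c("float32", "pcm16"),
                      rate = NULL) {
  bit_depth <- match.arg(bit_depth)
  if (inherits(recording, "pcg_recording")) {
    x <- recording$samples
    fs <- recording$sampling_rate
  } else {
    x <- as.numeric(recording)
    fs <- rate %||% stop("rate required when writing a bare vector")
  }

  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  if (bit_depth == "pcm16") {
    q <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
    bytes_per <- 2L
    audio_format <- 1L
  } else {
    bytes_per <- 4L
    audio_format <- 3L
  }
  data_size <- n * bytes_per

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_format, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")          # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == "pcm16") {
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
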