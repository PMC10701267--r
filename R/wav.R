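#' Read a PCM WAV file as a PCG recording
#'
#' Parses a RIFF/WAVE file containing integer PCM (8/16/32-bit) or IEEE
#' float samples. Samples are rescaled to `[-1, 1]`. Only the first channel
#' of a multi-channel file is kept (with a warning); heart-sound recorders
#' produce mono audio.
#'
#' @param path Path to a `.wav` file.
#' @param record_id Identifier stored on the record; defaults to the file
#'   name without extension.
#' @return A [pcg_record()].
#' @export
read_wav <- function(path, record_id = NULL) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  if (file.size(path) < 44L) stop("not a WAV file (truncated): ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }

  fmt <- NULL
  samples <- NULL
  repeat {
    chunk_id <- readChar(con, 4L, useBytes = TRUE)
    if (length(chunk_id) == 0L || nchar(chunk_id) < 4L) break
    chunk_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(chunk_id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", chunk_size + chunk_size %% 2L)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1L, 2L,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(raw_fmt[3:4], "integer", 1L, 2L,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1L, 4L,
                              endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1L, 2L,
                       signed = FALSE, endian = "little")
      )
    } else if (identical(chunk_id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt: ", path)
      samples <- read_wav_data(con, chunk_size, fmt)
      break
    } else {
      invisible(readBin(con, "raw", chunk_size + chunk_size %% 2L))
    }
  }
  if (is.null(fmt) || is.null(samples)) {
    stop("malformed WAV (missing fmt or data chunk): ", path)
  }
  if (fmt$n_channels > 1L) {
    warning("multi-channel WAV; using channel 0 only: ", path)
    samples <- samples[seq(1L, length(samples), by = fmt$n_channels)]
  }
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pcg_record(samples, fmt$sample_rate, record_id = record_id)
}

read_wav_data <- function(con, n_bytes, fmt) {
  bytes_per <- fmt$bits %/% 8L
  n <- n_bytes %/% bytes_per
  if (fmt$audio_format == 3L) {            # IEEE float
    x <- readBin(con, "double", n, size = bytes_per, endian = "little")
    return(x)
  }
  if (fmt$audio_format != 1L) stop("unsupported WAV encoding: ", fmt$audio_format)
  if (fmt$bits == 8L) {
    x <- readBin(con, "integer", n, size = 1L, signed = FALSE)
    (x - 128) / 128
  } else if (fmt$bits == 16L) {
    x <- readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "little")
    pmax(x / 32767, -1)  # same full-scale constant the writer uses
  } else if (fmt$bits == 32L) {
    x <- readBin(con, "integer", n, size = 4L, endian = "little")
    x / 2147483648
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits)
  }
}

#' Write a PCG recording to a 16-bit PCM WAV file
#'
#' Amplitudes outside `[-1, 1]` are clipped before quantization.
#'
#' @param record A [pcg_record()] (or numeric vector with `sampling_rate`).
#' @param path Output path.
#' @param sampling_rate Required when `record` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(record, path, sampling_rate = NULL) {
  if (is.numeric(record)) {
    record <- pcg_record(record, sampling_rate, record_id = "unnamed")
  }
  x <- pmin(1, pmax(-1, record$samples))
  q <- as.integer(round(x * 32767))
  n_bytes <- length(q) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(record$sampling_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(record$sampling_rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")   # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}
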