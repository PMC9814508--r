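#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the formats heart-sound corpora use:
#' PCM 16-bit, PCM 32-bit and IEEE float (32/64-bit), single channel.
#' Integer samples are rescaled by full scale so the result always lies in
#' `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in `[-1, 1]`) and
#'   `sample_rate_hz` (integer).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  readBin(con, "integer", 1, 4, endian = "little") # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, 2,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4,
                              endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2) # skip chunk (word-aligned)
      next
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (fmt$n_channels != 1L) {
    stop("only mono WAV is supported, got ", fmt$n_channels, " channels",
         call. = FALSE)
  }

  samples <- switch(
    as.character(fmt$audio_format),
    "1" = { # integer PCM
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", length(data_raw) / 2, 2,
                signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 32L) {
        readBin(data_raw, "integer", length(data_raw) / 4, 4,
                endian = "little") / 2147483648
      } else {
        stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
      }
    },
    "3" = { # IEEE float
      readBin(data_raw, "double", length(data_raw) / (fmt$bits / 8),
              fmt$bits / 8, endian = "little")
    },
    stop("unsupported WAV audio format code: ", fmt$audio_format,
         call. = FALSE)
  )
  list(samples = as.numeric(samples),
       sample_rate_hz = as.integer(fmt$sample_rate))
}

#' Write a mono WAV file
#'
#' Writes 16-bit PCM (default) or 32-bit IEEE float. Samples outside
#' `[-1, 1]` are clipped before integer quantisation.
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate_hz, path, bits = 16L) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate_hz > 0)
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32", call. = FALSE)
  fmt_code <- if (bits == 16L) 1L else 3L
  bytes_per <- bits %/% 8L
  data_size <- length(samples) * bytes_per

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little") # mono
  writeBin(as.integer(sample_rate_hz), con, 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16L) {
    x <- pmin(pmax(samples, -1), 32767 / 32768)
    writeBin(as.integer(round(x * 32768)), con, 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  }
  invisible(path)
}
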