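#' Read a mono WAV file as a voltage waveform
#'
#' Minimal RIFF/WAVE reader for the two encodings this package writes:
#' 16-bit integer PCM (samples scaled by a declared full-scale voltage) and
#' 32-bit IEEE float (samples are volts directly).
#'
#' @param path path to a mono WAV file.
#' @param full_scale_voltage voltage corresponding to integer full scale
#'   (32767) for 16-bit PCM files; ignored for float files.
#' @return a list with `samples` (numeric, volts) and `fs` (Hz).
#' @export
read_wav <- function(path, full_scale_voltage = 1.0) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        fs           = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt")
      if (fmt$channels != 1L) stop("only mono WAV supported")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", sz / 2, 2, signed = TRUE,
                     endian = "little")
        samples <- x / 32767 * full_scale_voltage
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", sz / 4, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$audio_format,
             ", ", fmt$bits, " bits)")
      }
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk in ", path)
  list(samples = samples, fs = fmt$fs)
}

#' Write a mono voltage waveform as a WAV file
#'
#' @param samples numeric vector of voltages.
#' @param fs sampling rate (Hz).
#' @param path output path.
#' @param format `"pcm16"` (16-bit PCM, scaled by `full_scale_voltage`) or
#'   `"float32"` (samples stored as volts).
#' @param full_scale_voltage voltage mapped to integer full scale for
#'   `"pcm16"`; samples exceeding it are clipped with a warning.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path, format = c("pcm16", "float32"),
                      full_scale_voltage = 1.0) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  if (format == "pcm16") {
    bytes_per <- 2L; audio_fmt <- 1L; bits <- 16L
  } else {
    bytes_per <- 4L; audio_fmt <- 3L; bits <- 32L
  }
  data_sz <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(audio_fmt, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, 4, endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (format == "pcm16") {
    x <- samples / full_scale_voltage
    if (any(abs(x) > 1)) {
      warning("samples exceed full-scale voltage; clipping")
      x <- pmin(1, pmax(-1, x))
    }
    writeBin(as.integer(round(x * 32767)), con, 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  }
  invisible(path)
}
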