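# Minimal mono RIFF/WAVE reader and writer (16-bit integer PCM and 32-bit
# float), sufficient for hydrophone recordings and synthetic songs.

#' Write a mono WAV file
#'
#' @param waveform Numeric waveform; for 16-bit output it is clipped to
#'   [-1, 1] and scaled to integer full range.
#' @param path Output file path.
#' @param sampling_rate Sampling rate in Hz.
#' @param format `"pcm16"` or `"float32"`.
#' @export
write_wav <- function(waveform, path, sampling_rate,
                      format = c("pcm16", "float32")) {
  format <- match.arg(format)
  n <- length(waveform)
  if (format == "pcm16") {
    bytes_per <- 2L; fmt_code <- 1L; bits <- 16L
  } else {
    bytes_per <- 4L; fmt_code <- 3L; bits <- 32L
  }
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(sampling_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sampling_rate * bytes_per), con, size = 4,
           endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- as.integer(round(pmax(pmin(waveform, 1), -1) * 32767))
    writeBin(x, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(waveform), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports 16-bit integer PCM and 32-bit float, as written by
#' [write_wav()].
#'
#' @param path WAV file path.
#' @return List: `waveform` (numeric, 16-bit data scaled to [-1, 1]),
#'   `sampling_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt_code <- NULL; sr <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      if (channels != 1) stop("only mono WAV is supported")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      extra <- size - 16
      if (extra > 0) readBin(con, raw(), n = extra)
    } else if (id == "data") {
      if (fmt_code == 1 && bits == 16) {
        data <- readBin(con, integer(), n = size / 2, size = 2,
                        signed = TRUE, endian = "little") / 32767
      } else if (fmt_code == 3 && bits == 32) {
        data <- readBin(con, numeric(), n = size / 4, size = 4,
                        endian = "little")
      } else {
        stop("unsupported WAV format (need 16-bit PCM or 32-bit float)")
      }
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(data)) stop("no data chunk found in ", path)
  list(waveform = data, sampling_rate = sr)
}
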