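#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the single-channel 16-bit PCM files the
#' pipeline produces and consumes. Samples are returned as doubles in
#' [-1, 1).
#'
#' @param path path to a `.wav` file.
#' @return list with `samples` (numeric vector, full scale = 1) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  sample_rate <- NULL
  bits <- NULL
  channels <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, size = 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(sample_rate) || is.null(samples)) {
    stop("malformed WAV (missing fmt or data chunk): ", path)
  }
  if (!identical(channels, 1L)) stop("only mono WAV supported, got ",
                                     channels, " channels")
  if (!identical(bits, 16L)) stop("only 16-bit PCM supported, got ",
                                  bits, " bits")
  list(samples = samples / 32768, sample_rate = sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are clipped to [-1, 1) and quantised to 16 bits. Writing then
#' reading a quantised signal reproduces it exactly, which is what makes
#' synthesized scenes byte-reproducible on disk.
#'
#' @param samples numeric vector, full scale = 1.
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  pcm <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
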