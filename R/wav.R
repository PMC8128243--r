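# Minimal RIFF/WAVE I/O (PCM 16-bit and IEEE float 32-bit), little-endian.

#' Write a waveform to a WAV file
#'
#' @param samples Numeric vector (mono) or matrix with one column per
#'   channel, full-scale `[-1, 1]`.
#' @param fs_hz Sample rate, Hz.
#' @param path Output path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs_hz, path, bits = 16) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32")
  n_ch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  block <- n_ch * bits / 8
  data_len <- length(interleaved) * bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  wu32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wu16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); wu32(36 + data_len)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wu32(16)
  wu16(if (bits == 16) 1 else 3)       # PCM or IEEE float
  wu16(n_ch); wu32(fs_hz); wu32(fs_hz * block); wu16(block); wu16(bits)
  writeChar("data", con, eos = NULL); wu32(data_len)
  if (bits == 16) {
    writeBin(as.integer(round(pmax(-1, pmin(1, interleaved)) * 32767)),
             con, size = 2, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Supports the PCM 16-bit and IEEE float 32-bit files written by
#' [write_wav()] (and any canonical-layout WAV of those formats).
#'
#' @param path WAV file path.
#' @return List with `samples` (matrix, one column per channel, full scale
#'   `[-1, 1]`) and `fs_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ru32 <- function() readBin(con, "integer", size = 4, endian = "little")
  ru16 <- function() readBin(con, "integer", size = 2, endian = "little",
                             signed = FALSE)
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  ru32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    len <- ru32()
    if (id == "fmt ") {
      fmt <- list(tag = ru16(), n_ch = ru16(), fs = ru32())
      ru32(); ru16()
      fmt$bits <- ru16()
      if (len > 16) readBin(con, "raw", len - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt in ", path)
      n <- len / (fmt$bits / 8)
      x <- if (fmt$bits == 16 && fmt$tag == 1)
        readBin(con, "integer", n, size = 2, endian = "little") / 32767
      else if (fmt$bits == 32 && fmt$tag == 3)
        readBin(con, "double", n, size = 4, endian = "little")
      else stop("unsupported WAV format (tag ", fmt$tag, ", ",
                fmt$bits, " bits)")
      return(list(samples = matrix(x, ncol = fmt$n_ch, byrow = TRUE),
                  fs_hz = fmt$fs))
    } else {
      readBin(con, "raw", len + len %% 2)
    }
  }
}
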