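# Minimal 16-bit PCM RIFF WAV I/O. None of the installed packages read or
# write WAV, and the recorder format here is plain uncompressed PCM, so a
# small codec is kept in-package. Samples are exchanged as numeric matrices
# in [-1, 1], one column per channel.

#' Write a 16-bit PCM WAV file
#'
#' Multi-channel samples are written interleaved. Values are expected in
#' [-1, 1]; anything outside is clipped. By default the signal is peak
#' normalized to -6 dBFS before quantization (headroom against clipping
#' while using most of the 16-bit range, matching the recorder bit depth).
#'
#' @param x numeric vector (mono) or matrix with one column per channel.
#' @param path output file path.
#' @param fs sampling rate in Hz.
#' @param normalize logical; peak-normalize to -6 dBFS before writing.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs, normalize = TRUE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  stopifnot(is.matrix(x), is.numeric(x), fs > 0)
  if (normalize) {
    pk <- max(abs(x))
    if (pk > 0) x <- x / pk * 10^(-6 / 20)
  }
  x <- clamp(x, -1, 1)
  n_ch <- ncol(x)
  n <- nrow(x)
  pcm <- as.integer(round(t(x) * 32767))  # interleave channels
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n * n_ch
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * n_ch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path input file path.
#' @return list with `samples` (matrix, one column per channel, values in
#'   [-1, 1]) and `fs` (sampling rate in Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop_arg("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop_arg("not a WAVE file: ", path)
  fs <- NULL; n_ch <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop_arg("only PCM WAV is supported")
      n_ch <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stop_arg("only 16-bit WAV is supported")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2,
                     signed = TRUE, endian = "little")
      samples <- matrix(pcm / 32767, ncol = n_ch, byrow = TRUE)
      break
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2))
    }
  }
  if (is.null(samples)) stop_arg("no data chunk found in ", path)
  list(samples = samples, fs = fs)
}
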