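#' Write a waveform as 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE writer for the stimulus waveforms (no installed
#' package in this stack writes WAV). Samples outside [-1, 1] are
#' clipped.
#'
#' @param wave Numeric matrix, samples x channels, in [-1, 1].
#' @param path Output path.
#' @param sr Sample rate in Hz.
#' @export
write_wav <- function(wave, path, sr) {
  if (is.null(dim(wave))) wave <- matrix(wave, ncol = 1)
  n_ch <- ncol(wave)
  pcm <- as.integer(round(pmax(-1, pmin(1, t(wave))) * 32767))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * n_ch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Counterpart of [write_wav()]; supports plain PCM files only.
#'
#' @param path Input path.
#' @return List with `wave` (samples x channels matrix in [-1, 1]) and
#'   `sr`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file")
  sr <- NULL; n_ch <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      n_ch <- fmt[2]
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit WAV supported")
    } else if (id == "data") {
      samples <- readBin(con, integer(), n = sz / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  list(wave = t(matrix(samples / 32767, nrow = n_ch)), sr = sr)
}
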