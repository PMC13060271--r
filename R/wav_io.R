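# Minimal single-channel 16-bit PCM WAV I/O.
# No WAV package ships with the analysis stack and the format is a plain
# RIFF container, so a small reader/writer is bundled rather than adding
# a dependency. Mono PCM16 only: enough for impulse-response work.

#' Read a mono 16-bit PCM WAV file
#'
#' @param path File path.
#' @return List `samples` (numeric in [-1, 1]) and `sampling_rate` (Hz).
#' @export
read_wav_mono <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAV file")
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
      if (fmt[1] != 1 || bits != 16 || channels != 1)
        stop("only mono 16-bit PCM WAV is supported")
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(samples) || is.null(fs)) stop("malformed WAV file")
  list(samples = samples / 32768, sampling_rate = fs)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector; values are clipped to [-1, 1].
#' @param sampling_rate Hz.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_wav_mono <- function(samples, sampling_rate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sampling_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sampling_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
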