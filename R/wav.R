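# Minimal RIFF/PCM WAV I/O (16-bit mono), enough to exchange sensor streams
# with other tools. Amplitudes are scaled by 32767 so that a write/read
# round-trip of in-range samples is exact to within one LSB.

#' Write samples to a mono 16-bit PCM WAV file
#'
#' @param samples numeric amplitudes in \[-1, 1\] (values outside are clipped).
#' @param fs sampling rate, Hz.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeWav <- function(samples, fs, path) {
  stopInvalid(fs <= 0, "fs must be > 0")
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w4(36 + 2 * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w4(16)
  w2(1); w2(1)                      # PCM, mono
  w4(round(fs)); w4(round(fs) * 2)  # sample rate, byte rate
  w2(2); w2(16)                     # block align, bits per sample
  writeChar("data", con, eos = NULL); w4(2 * n)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric in \[-1, 1\]) and `fs` (Hz).
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r4 <- function() readBin(con, integer(), size = 4, endian = "little")
  r2 <- function() readBin(con, integer(), size = 2, endian = "little")
  stopInvalid(readChar(con, 4) != "RIFF", "not a RIFF file")
  r4()
  stopInvalid(readChar(con, 4) != "WAVE", "not a WAVE file")
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- r4()
    if (id == "fmt ") {
      fmt <- r2(); channels <- r2(); fs <- r4(); r4(); r2(); bits <- r2()
      stopInvalid(fmt != 1, "only PCM WAV is supported")
      if (size > 16) readBin(con, raw(), size - 16)
    } else if (id == "data") {
      stopInvalid(is.null(bits), "malformed WAV: data before fmt")
      stopInvalid(bits != 16, "only 16-bit PCM is supported")
      stopInvalid(channels != 1, "only mono WAV is supported")
      samples <- readBin(con, integer(), n = size / 2, size = 2,
                         endian = "little") / 32767
      break
    } else {
      readBin(con, raw(), size + size %% 2)
    }
  }
  stopInvalid(is.null(samples), "no data chunk found")
  list(samples = samples, fs = fs)
}

#' Write a synthetic stream's ground-truth log as JSON
#'
#' Sidecar for WAV streams written with [writeWav()]: per event the onset
#' sample, duration, species and true fundamental, plus the generator seed.
#'
#' @param log data.frame from [synthStream()].
#' @param path output file.
#' @param seed generator seed to record (optional).
#' @return `path`, invisibly.
#' @export
writeEventLog <- function(log, path, seed = NULL) {
  jsonlite::write_json(list(seed = seed, events = log), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
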