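#' Hamming window (periodic convention)
#'
#' `w[k] = 0.54 - 0.46 * cos(2*pi*k/n)`, k = 0..n-1. The periodic convention
#' is fixed so that signatures are bit-stable across implementations.
#'
#' @param n window length.
#' @return numeric vector of length `n`.
#' @export
hammingWindow <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / n)
}

#' Raw magnitude spectrum of an event frame
#'
#' Applies a Hamming window to the frame, computes a `nFft`-point FFT and
#' returns the magnitudes of the first `nFft/2` bins, with the lowest
#' `dcCutBins` bins zeroed (emulating the analog high-pass that removes the
#' insect's slow body-movement component). Frames shorter than `nFft` are
#' windowed over their own length and zero-padded; frames longer than `nFft`
#' are an error.
#'
#' @param frame numeric amplitude sequence, length <= `nFft`.
#' @param nFft FFT size (default 512).
#' @param dcCutBins number of lowest bins to zero (default 3, i.e. roughly
#'   0-23 Hz at the 4 kHz / 512-point defaults).
#' @return numeric vector of `nFft/2` non-negative magnitudes. Bin `b`
#'   (0-based) is centered at `b * fs / nFft` Hz.
#' @examples
#' f <- sin(2 * pi * 23 * (0:511) / 512)  # exactly bin 23
#' which.max(magnitudeSpectrum(f)) - 1
#' @export
magnitudeSpectrum <- function(frame, nFft = 512L, dcCutBins = 3L) {
  n <- length(frame)
  stopInvalid(n == 0L || n > nFft,
              sprintf("frame length must be in 1..%d", nFft))
  x <- frame * hammingWindow(n)
  if (n < nFft) x <- c(x, numeric(nFft - n))
  mags <- Mod(fft(x))[seq_len(nFft / 2)]
  if (dcCutBins > 0) mags[seq_len(min(dcCutBins, length(mags)))] <- 0
  mags
}

#' Normalize a magnitude spectrum to unit Euclidean norm
#'
#' Divides every coefficient by the Euclidean norm of the vector, the trap's
#' gain-invariant normalization: the signature of a recording does not depend
#' on the analog gain applied to it.
#'
#' @param mags non-negative magnitude sequence with at least one positive
#'   entry.
#' @return numeric vector of the same length with unit L2 norm.
#' @examples
#' normalizeSpectrum(c(3, 4, rep(0, 254)))[1:2]
#' @export
normalizeSpectrum <- function(mags) {
  stopInvalid(any(mags < 0), "magnitudes must be non-negative")
  nrm <- sqrt(sum(mags^2))
  if (nrm == 0)
    stop("degenerate spectrum: all-zero magnitudes (drop this event)",
         call. = FALSE)
  mags / nrm
}

#' Convert an event frame to its spectral signature
#'
#' Composition of [magnitudeSpectrum()] and [normalizeSpectrum()]. For frames
#' longer than `nFft` (pretriggered events carry the previous frame too) the
#' contiguous `nFft`-sample window of maximal energy is used, so the window
#' covers the insect pass rather than an arbitrary frame boundary and the
#' feature contract (one `nFft`-point FFT) is the same for every event.
#'
#' @param frame numeric amplitude sequence.
#' @inheritParams magnitudeSpectrum
#' @return numeric signature of `nFft/2` non-negative coefficients with unit
#'   L2 norm.
#' @export
eventToSignature <- function(frame, nFft = 512L, dcCutBins = 3L) {
  if (length(frame) > nFft) {
    cs <- cumsum(c(0, frame^2))
    wsum <- cs[(nFft + 1L):length(cs)] - cs[seq_len(length(cs) - nFft)]
    start <- which.max(wsum)
    frame <- frame[start:(start + nFft - 1L)]
  }
  normalizeSpectrum(magnitudeSpectrum(frame, nFft = nFft,
                                      dcCutBins = dcCutBins))
}

#' Construct a SpectrumSet
#'
#' @param spectra numeric matrix, rows = events, columns = `nFft/2` frequency
#'   bins; every row must already be a unit-L2-norm signature.
#' @param fs sampling rate, Hz.
#' @param nFft FFT size used to produce the signatures.
#' @param eventData optional data.frame of per-event metadata (species,
#'   f0_true, onset_sample, ...), one row per event.
#' @return a [SpectrumSet].
#' @examples
#' s <- eventToSignature(synthEvent(speciesPreset("b_oleae"), 128, seed = 1)@samples)
#' ss <- SpectrumSet(rbind(s), eventData = data.frame(species = "b_oleae"))
#' @export
SpectrumSet <- function(spectra, fs = 4000, nFft = 512L, eventData = NULL) {
  spectra <- as.matrix(spectra)
  if (is.null(eventData)) eventData <- data.frame(row.names = seq_len(nrow(spectra)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signature = t(spectra)),
    rowData = S4Vectors::DataFrame(
      freqHz = (seq_len(ncol(spectra)) - 1) * fs / nFft),
    colData = S4Vectors::DataFrame(eventData),
    metadata = list(fs = fs, nFft = as.integer(nFft))
  )
  new("SpectrumSet", se)
}

#' Featurize detected events into a SpectrumSet
#'
#' Runs [eventToSignature()] on every event frame. Events with a degenerate
#' (all-zero) spectrum are dropped with a warning.
#'
#' @param frames numeric matrix of event frames (one row per event), as
#'   returned by [detectEvents()].
#' @param config a [DetectionConfig] (supplies fs and the frame length).
#' @param dcCutBins lowest bins to zero, see [magnitudeSpectrum()].
#' @param eventData optional per-event metadata data.frame.
#' @param samples optional list of full event extents (the `samples` element
#'   [detectEvents()] returns in pretrigger mode); when given, signatures are
#'   computed from these instead of the bare event frames.
#' @return a [SpectrumSet].
#' @export
featurizeEvents <- function(frames, config = detectionConfig(),
                            dcCutBins = 3L, eventData = NULL,
                            samples = NULL) {
  nFft <- config@frameLen
  n <- if (is.null(samples)) nrow(frames) else length(samples)
  sigs <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    x <- if (is.null(samples)) frames[i, ] else samples[[i]]
    res <- tryCatch(
      eventToSignature(x, nFft = nFft, dcCutBins = dcCutBins),
      error = function(e) NULL)
    ok[i] <- !is.null(res)
    if (ok[i]) sigs[[i]] <- res
  }
  if (!all(ok))
    warning(sum(!ok), " event(s) with degenerate spectra dropped")
  mat <- do.call(rbind, sigs[ok])
  if (is.null(mat)) mat <- matrix(numeric(), 0, nFft / 2)
  if (!is.null(eventData)) eventData <- eventData[ok, , drop = FALSE]
  SpectrumSet(mat, fs = config@fs, nFft = nFft, eventData = eventData)
}

#' Detect and featurize all events in a stream
#'
#' Convenience composition of [detectEvents()] and [featurizeEvents()]:
#' returns the signatures of every triggered event in the stream. This is how
#' reference (training) spectra should be captured — through the same
#' framing/triggering front end that will process unknown events — so that
#' codebook prototypes and incoming signatures share the same acquisition
#' geometry.
#'
#' @param stream numeric sample stream.
#' @param config a [DetectionConfig].
#' @param dcCutBins lowest bins to zero, see [magnitudeSpectrum()].
#' @return a [SpectrumSet] with `onset_sample` in its event metadata.
#' @export
streamSignatures <- function(stream, config = detectionConfig(),
                             dcCutBins = 3L) {
  det <- detectEvents(stream, config)
  featurizeEvents(det$frames, config, dcCutBins = dcCutBins,
                  eventData = det$log, samples = det$samples)
}

#' @rdname spectra
#' @export
setMethod("spectra", "SpectrumSet", function(x) {
  t(SummarizedExperiment::assay(x, "signature"))
})

#' Frequency bin width of a SpectrumSet
#'
#' @param x a [SpectrumSet].
#' @return `fs / nFft` in Hz (7.8125 at the 4 kHz / 512-point defaults).
#' @export
binHz <- function(x) {
  md <- S4Vectors::metadata(x)
  md$fs / md$nFft
}

#' @describeIn SpectrumSet-class display summary
#' @param object a SpectrumSet
#' @export
setMethod("show", "SpectrumSet", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf("SpectrumSet: %d signatures x %d bins (fs %g Hz, %d-point FFT, bin %g Hz)\n",
              ncol(object), nrow(object), md$fs, md$nFft, md$fs / md$nFft))
  cd <- names(SummarizedExperiment::colData(object))
  if (length(cd)) cat("  event metadata:", paste(cd, collapse = ", "), "\n")
})

#' Write / read a signature matrix as CSV
#'
#' The CSV has one row per event and `nFft/2` magnitude columns, preceded by
#' a comment header recording `fs` and `nFft`. Event metadata columns, if
#' present, are appended after the magnitude columns.
#'
#' @param x a [SpectrumSet].
#' @param path output file.
#' @return `writeSpectra` returns `path` invisibly; `readSpectra` returns a
#'   [SpectrumSet].
#' @export
writeSpectra <- function(x, path) {
  md <- S4Vectors::metadata(x)
  mat <- spectra(x)
  colnames(mat) <- paste0("bin", seq_len(ncol(mat)) - 1)
  df <- as.data.frame(mat)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (ncol(cd)) df <- cbind(df, cd)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g n_fft=%d", md$fs, md$nFft), con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectra
#' @export
readSpectra <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("# fs=([0-9.]+) n_fft=([0-9]+)", hdr))[[1]]
  stopInvalid(length(m) != 3, "missing '# fs=... n_fft=...' header")
  fs <- as.numeric(m[2]); nFft <- as.integer(m[3])
  df <- read.table(path, sep = ",", header = TRUE, comment.char = "#")
  binCols <- grep("^bin[0-9]+$", names(df))
  meta <- df[, setdiff(seq_along(df), binCols), drop = FALSE]
  SpectrumSet(as.matrix(df[, binCols]), fs = fs, nFft = nFft,
              eventData = if (ncol(meta)) meta else NULL)
}
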