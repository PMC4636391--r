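#' Build an acquisition/detection configuration
#'
#' @param frameLen frame length in samples (default 512, the firmware's
#'   buffer: 128 ms at 4 kHz).
#' @param fs sampling rate, Hz (default 4000).
#' @param rmsThreshold RMS trigger threshold in amplitude units. The firmware
#'   uses a pre-defined constant; prefer calibrating with
#'   [calibrateRmsThreshold()] on a noise-only segment.
#' @param adcBits ADC resolution (default 10).
#' @param hop frame hop in samples (default `frameLen`, i.e. non-overlapping
#'   frames as in a single-ADC circular-buffer loop).
#' @param pretrigger if TRUE, prepend the previous frame to each event's
#'   samples (recovers the pre-trigger buffer the firmware discards).
#' @return a validated [DetectionConfig].
#' @examples
#' detectionConfig(rmsThreshold = 0.05)
#' @export
detectionConfig <- function(frameLen = 512L, fs = 4000, rmsThreshold = 0.05,
                            adcBits = 10L, hop = frameLen,
                            pretrigger = FALSE) {
  new("DetectionConfig", frameLen = as.integer(frameLen), fs = as.numeric(fs),
      rmsThreshold = as.numeric(rmsThreshold), adcBits = as.integer(adcBits),
      hop = as.integer(hop), pretrigger = isTRUE(pretrigger))
}

#' Root-mean-square amplitude of a frame
#'
#' @param frame non-empty numeric amplitude sequence.
#' @return `sqrt(mean(frame^2))`.
#' @examples
#' rms(rep(0.5, 100))
#' @export
rms <- function(frame) {
  stopInvalid(length(frame) == 0, "frame must be non-empty")
  sqrt(mean(frame^2))
}

#' Calibrate the RMS trigger threshold from a noise-only segment
#'
#' The firmware uses a pre-defined constant threshold; this helper sets it to
#' `factor` times the RMS of a segment known to contain no events.
#'
#' @param noiseSegment numeric samples containing no insect passes.
#' @param factor multiplier over the noise RMS (default 5).
#' @return numeric threshold.
#' @export
calibrateRmsThreshold <- function(noiseSegment, factor = 5) {
  factor * rms(noiseSegment)
}

#' Detect events by frame-wise RMS triggering
#'
#' Scans the stream in frames of `frameLen` samples at hop `hop` and triggers
#' on every frame whose RMS strictly exceeds `rmsThreshold`. Runs of
#' consecutive triggered frames are merged into a single event (an insect
#' pass can span several frames); the first triggered frame of the run is
#' kept as the event frame, replicating the firmware, which analyzes only the
#' buffer that fired the trigger. With `pretrigger = TRUE` each event
#' additionally carries its full sample extent — the frame preceding the
#' trigger plus every triggered frame of the run — recovering the data the
#' firmware discards.
#'
#' @param stream numeric sample stream of length >= `frameLen`.
#' @param config a [DetectionConfig].
#' @return list with:
#'   * `log`: data.frame with one row per event — `onset_sample` (1-based
#'     start of the event frame), `rms` (RMS of the event frame), `n_frames`
#'     (triggered frames merged into the event);
#'   * `frames`: numeric matrix, one row per event, holding the event frame;
#'   * `samples`: only when `pretrigger = TRUE`, a list holding each event's
#'     full extent (pre-trigger frame + all triggered frames).
#' @examples
#' st <- synthStream(list(speciesPreset("b_oleae")), 2, seed = 1, noiseSd = 0)
#' detectEvents(st$samples, detectionConfig(rmsThreshold = 0.05))$log
#' @export
detectEvents <- function(stream, config = detectionConfig()) {
  validObject(config)
  fl <- config@frameLen
  stopInvalid(length(stream) < fl, "stream shorter than one frame")
  starts <- seq.int(1L, length(stream) - fl + 1L, by = config@hop)
  rmsVals <- vapply(starts, function(s) rms(stream[s:(s + fl - 1L)]), numeric(1))
  hit <- which(rmsVals > config@rmsThreshold)
  if (length(hit) == 0L) {
    out <- list(
      log = data.frame(onset_sample = integer(), rms = numeric(),
                       n_frames = integer()),
      frames = matrix(numeric(), nrow = 0, ncol = fl))
    if (config@pretrigger) out$samples <- list()
    return(out)
  }
  newRun <- c(TRUE, diff(hit) != 1L)
  runStart <- hit[newRun]
  runId <- cumsum(newRun)
  nFrames <- as.integer(table(runId))
  runEnd <- hit[cumsum(nFrames)]
  onset <- starts[runStart]
  frames <- matrix(0, nrow = length(onset), ncol = fl)
  for (i in seq_along(onset))
    frames[i, ] <- stream[onset[i]:(onset[i] + fl - 1L)]
  out <- list(log = data.frame(onset_sample = as.integer(onset),
                               rms = rmsVals[runStart], n_frames = nFrames),
              frames = frames)
  if (config@pretrigger) {
    out$samples <- lapply(seq_along(onset), function(i) {
      s0 <- max(1L, onset[i] - fl)
      e0 <- min(length(stream), starts[runEnd[i]] + fl - 1L)
      stream[s0:e0]
    })
  }
  out
}

#' @describeIn DetectionConfig-class display summary
#' @param object a DetectionConfig
#' @export
setMethod("show", "DetectionConfig", function(object) {
  cat(sprintf(
    "DetectionConfig: %d-sample frames @ %g Hz (hop %d), RMS threshold %g, %d-bit ADC%s\n",
    object@frameLen, object@fs, object@hop, object@rmsThreshold,
    object@adcBits, if (object@pretrigger) ", pretrigger" else ""))
})
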