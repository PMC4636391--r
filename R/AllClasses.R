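#' @import methods
#' @importFrom stats fft kmeans rnorm runif sd var predict
#' @importFrom utils read.table write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Generative wingbeat parameters for one species
#'
#' A `SpeciesProfile` holds everything the harmonic simulator needs to draw
#' wingbeat events for one species: the band the fundamental frequency is
#' drawn from, the relative amplitude of each harmonic, the scale of the slow
#' within-event frequency drift, the mixture of flight-pass durations
#' (fast direct crossings vs slow strolling passes), and the depth of slow
#' amplitude modulation that emulates maneuvering through the light gate.
#'
#' @slot name character species label.
#' @slot f0Range numeric(2), closed interval of the fundamental frequency in Hz.
#' @slot harmonicWeights numeric, relative amplitude of harmonics h = 1..H;
#'   the first entry is the fundamental. Non-negative, at least one positive.
#' @slot f0JitterSd numeric, Hz; scale of the slow within-event drift of the
#'   instantaneous wingbeat frequency.
#' @slot durationModes data.frame with columns `minMs`, `maxMs`, `prob`; each
#'   row is one behavioral flight mode (a duration interval in ms and its
#'   probability). Probabilities sum to 1.
#' @slot amDepth numeric in [0, 1]; fractional depth of slow amplitude
#'   modulation.
#'
#' @seealso [speciesProfile()], [speciesPreset()]
#' @exportClass SpeciesProfile
setClass("SpeciesProfile",
  representation(
    name = "character",
    f0Range = "numeric",
    harmonicWeights = "numeric",
    f0JitterSd = "numeric",
    durationModes = "data.frame",
    amDepth = "numeric"
  )
)

setValidity("SpeciesProfile", function(object) {
  msg <- character()
  if (length(object@f0Range) != 2L || any(!is.finite(object@f0Range)))
    msg <- c(msg, "f0Range must be two finite values")
  else {
    if (object@f0Range[1] <= 0)
      msg <- c(msg, "f0Range lower bound must be > 0")
    if (object@f0Range[2] < object@f0Range[1])
      msg <- c(msg, "f0Range upper bound must be >= lower bound")
  }
  w <- object@harmonicWeights
  if (length(w) < 1L || any(w < 0) || !any(w > 0))
    msg <- c(msg, "harmonicWeights must be non-negative with at least one positive entry")
  if (object@f0JitterSd < 0)
    msg <- c(msg, "f0JitterSd must be >= 0")
  dm <- object@durationModes
  if (!all(c("minMs", "maxMs", "prob") %in% names(dm)))
    msg <- c(msg, "durationModes needs columns minMs, maxMs, prob")
  else {
    if (abs(sum(dm$prob) - 1) > 1e-8)
      msg <- c(msg, "durationModes probabilities must sum to 1")
    if (any(dm$minMs <= 0) || any(dm$maxMs < dm$minMs))
      msg <- c(msg, "durationModes intervals must be positive with maxMs >= minMs")
  }
  if (object@amDepth < 0 || object@amDepth > 1)
    msg <- c(msg, "amDepth must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' One optoacoustic sensor pass
#'
#' A `WingbeatEvent` is a single pass of an insect through the optical gate:
#' a vector of dimensionless amplitudes (nominal range [-1, 1]) at a known
#' sampling rate, with optional provenance metadata (species label, ground
#' truth fundamental frequency, ambient temperature).
#'
#' @slot samples numeric amplitude sequence.
#' @slot fs numeric sampling rate, Hz.
#' @slot species character label or NA.
#' @slot f0True numeric ground-truth fundamental, Hz, or NA.
#' @slot temperatureC numeric ambient temperature metadata, or NA.
#'
#' @exportClass WingbeatEvent
setClass("WingbeatEvent",
  representation(
    samples = "numeric",
    fs = "numeric",
    species = "character",
    f0True = "numeric",
    temperatureC = "numeric"
  ),
  prototype(species = NA_character_, f0True = NA_real_, temperatureC = NA_real_)
)

setValidity("WingbeatEvent", function(object) {
  msg <- character()
  if (length(object@samples) < 1L)
    msg <- c(msg, "samples must have length >= 1")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Acquisition-loop configuration
#'
#' Parameters of the embedded acquisition loop: frame length, sampling rate,
#' the RMS trigger threshold, ADC depth and frame hop. Defaults mirror the
#' trap firmware: non-overlapping 512-sample frames at 4 kHz, 10-bit ADC.
#'
#' @slot frameLen integer, samples per frame (default 512).
#' @slot fs numeric, Hz (default 4000).
#' @slot rmsThreshold numeric amplitude units; a frame whose RMS strictly
#'   exceeds this triggers an event.
#' @slot adcBits integer ADC resolution (default 10).
#' @slot hop integer frame hop in samples (default `frameLen`).
#' @slot pretrigger logical; if TRUE the previous frame is prepended to each
#'   event's samples, recovering the buffer the firmware discards.
#'
#' @exportClass DetectionConfig
setClass("DetectionConfig",
  representation(
    frameLen = "integer",
    fs = "numeric",
    rmsThreshold = "numeric",
    adcBits = "integer",
    hop = "integer",
    pretrigger = "logical"
  )
)

setValidity("DetectionConfig", function(object) {
  msg <- character()
  if (object@frameLen < 2L) msg <- c(msg, "frameLen must be >= 2")
  if (object@hop < 1L) msg <- c(msg, "hop must be >= 1")
  if (object@rmsThreshold < 0) msg <- c(msg, "rmsThreshold must be >= 0")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (object@adcBits < 2L) msg <- c(msg, "adcBits must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Set of spectral signatures
#'
#' `SpectrumSet` stores normalized magnitude-spectrum signatures for a set of
#' wingbeat events as a [SummarizedExperiment::SummarizedExperiment]: the
#' `"signature"` assay holds one unit-L2-norm column of `nFft/2` non-negative
#' coefficients per event, `rowData` carries the bin center frequencies, and
#' `colData` carries per-event metadata (species, ground-truth f0, onset).
#'
#' Use [SpectrumSet()] to construct one from an events-by-bins matrix and
#' [spectra()] to get that matrix back.
#'
#' @exportClass SpectrumSet
setClass("SpectrumSet", contains = "SummarizedExperiment")

setValidity("SpectrumSet", function(object) {
  msg <- character()
  if (!"signature" %in% SummarizedExperiment::assayNames(object))
    return("must contain a 'signature' assay")
  a <- SummarizedExperiment::assay(object, "signature")
  if (any(a < 0)) msg <- c(msg, "signature coefficients must be non-negative")
  if (ncol(a) > 0) {
    norms <- sqrt(colSums(a^2))
    if (any(abs(norms - 1) > 1e-9))
      msg <- c(msg, "every signature must have unit L2 norm (within 1e-9)")
  }
  md <- S4Vectors::metadata(object)
  if (!is.null(md$nFft) && nrow(a) != md$nFft / 2)
    msg <- c(msg, "number of bins must equal nFft/2")
  if (length(msg)) msg else TRUE
})

#' Prototype codebook with calibrated acceptance threshold
#'
#' A `Codebook` holds K unit-norm prototype spectra (K-means centroids,
#' re-normalized) for one species, together with the statistics of the
#' minimum L1 distances of the training spectra to the prototypes and the
#' resulting open-set acceptance threshold, mean + 3 standard deviations.
#'
#' @slot species character target species label.
#' @slot prototypes numeric matrix, K rows (prototypes) by nBins columns,
#'   each row unit L2 norm.
#' @slot muD numeric, mean of training minimum distances (NA if uncalibrated).
#' @slot sigmaD numeric, sample SD of training minimum distances.
#' @slot threshold numeric, `muD + 3 * sigmaD`.
#' @slot nTrain integer, number of training spectra.
#' @slot seed integer, RNG seed used for clustering.
#'
#' @exportClass Codebook
setClass("Codebook",
  representation(
    species = "character",
    prototypes = "matrix",
    muD = "numeric",
    sigmaD = "numeric",
    threshold = "numeric",
    nTrain = "integer",
    seed = "integer"
  ),
  prototype(muD = NA_real_, sigmaD = NA_real_, threshold = NA_real_,
            nTrain = 0L, seed = NA_integer_)
)

setValidity("Codebook", function(object) {
  msg <- character()
  if (nrow(object@prototypes) < 1L)
    msg <- c(msg, "codebook needs K >= 1 prototypes")
  norms <- sqrt(rowSums(object@prototypes^2))
  if (any(abs(norms - 1) > 1e-6))
    msg <- c(msg, "every prototype must be unit L2 norm")
  if (!is.na(object@threshold)) {
    if (is.na(object@muD) || is.na(object@sigmaD))
      msg <- c(msg, "calibrated codebook needs muD and sigmaD")
    else {
      if (object@muD < 0 || object@sigmaD < 0)
        msg <- c(msg, "muD and sigmaD must be >= 0")
      if (abs(object@threshold - (object@muD + 3 * object@sigmaD)) > 1e-9)
        msg <- c(msg, "threshold must equal muD + 3 * sigmaD")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Classification evaluation report
#'
#' Confusion matrix plus per-class and support-weighted precision, recall and
#' F1, in the layout of the trap's evaluation tables
#' (precision | recall | F1 | #recs with an Avg/total row).
#'
#' @slot labels character, ordered class names.
#' @slot confusion integer matrix; entry (i, j) counts items of true class i
#'   predicted as class j.
#' @slot perClass data.frame with columns precision, recall, f1, support.
#' @slot weighted named numeric: support-weighted precision, recall, f1.
#' @slot nTotal integer total number of items.
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(
    labels = "character",
    confusion = "matrix",
    perClass = "data.frame",
    weighted = "numeric",
    nTotal = "integer"
  )
)

setValidity("EvaluationReport", function(object) {
  msg <- character()
  cm <- object@confusion
  if (any(cm < 0) || any(cm != round(cm)))
    msg <- c(msg, "confusion entries must be non-negative integers")
  if (sum(cm) != object@nTotal)
    msg <- c(msg, "confusion total must equal nTotal")
  if (!identical(unname(rowSums(cm)), as.numeric(object@perClass$support)))
    msg <- c(msg, "row sums must equal class supports")
  if (length(msg)) msg else TRUE
})

#' Per-trap telemetry record
#'
#' The daily report a trap transmits: identifier, timestamp, total triggered
#' events, target-species matches, and the auxiliary sensor readings
#' (temperature, humidity, GPS coordinates, battery level).
#'
#' @slot trapId character trap identifier.
#' @slot timestamp character, ISO-8601.
#' @slot eventsTotal integer count of triggered events.
#' @slot matchesTotal integer count of target verdicts; never exceeds
#'   `eventsTotal`.
#' @slot temperatureC numeric degrees Celsius.
#' @slot humidityPct numeric relative humidity, [0, 100].
#' @slot latitude,longitude numeric decimal degrees.
#' @slot batteryPct numeric battery level, [0, 100].
#'
#' @exportClass TelemetryRecord
setClass("TelemetryRecord",
  representation(
    trapId = "character",
    timestamp = "character",
    eventsTotal = "integer",
    matchesTotal = "integer",
    temperatureC = "numeric",
    humidityPct = "numeric",
    latitude = "numeric",
    longitude = "numeric",
    batteryPct = "numeric"
  )
)

setValidity("TelemetryRecord", function(object) {
  msg <- character()
  if (object@eventsTotal < 0L)
    msg <- c(msg, "eventsTotal must be >= 0")
  if (object@matchesTotal < 0L || object@matchesTotal > object@eventsTotal)
    msg <- c(msg, "matchesTotal must lie in [0, eventsTotal]")
  if (!is.na(object@humidityPct) &&
      (object@humidityPct < 0 || object@humidityPct > 100))
    msg <- c(msg, "humidityPct must lie in [0, 100]")
  if (!is.na(object@batteryPct) &&
      (object@batteryPct < 0 || object@batteryPct > 100))
    msg <- c(msg, "batteryPct must lie in [0, 100]")
  if (!is.na(object@latitude) && abs(object@latitude) > 90)
    msg <- c(msg, "latitude must lie in [-90, 90]")
  if (!is.na(object@longitude) && abs(object@longitude) > 180)
    msg <- c(msg, "longitude must lie in [-180, 180]")
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}", object@timestamp))
    msg <- c(msg, "timestamp must be ISO-8601 (YYYY-MM-DDTHH:MM:SS...)")
  if (length(msg)) msg else TRUE
})
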