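#' Construct a species wingbeat profile
#'
#' @param name species label.
#' @param f0Range numeric(2), Hz; the fundamental of each event is drawn
#'   uniformly from this closed interval.
#' @param harmonicWeights relative amplitudes of harmonics 1..H (first entry
#'   is the fundamental).
#' @param f0JitterSd Hz; scale of the slow within-event drift of the
#'   instantaneous wingbeat frequency (0 = perfectly steady wingbeat).
#' @param durationModes data.frame with columns `minMs`, `maxMs`, `prob`; one
#'   row per behavioral flight mode. Defaults to the two observed modes:
#'   fast direct crossings (30-50 ms) and slow strolling passes (50-300 ms),
#'   equally likely.
#' @param amDepth fraction in [0, 1] of slow amplitude modulation emulating
#'   maneuvering passes.
#' @return a validated [SpeciesProfile].
#' @examples
#' p <- speciesProfile("toy", c(180, 200), c(1, 0.5))
#' ev <- synthEvent(p, durationMs = 128, seed = 1)
#' @export
speciesProfile <- function(name, f0Range, harmonicWeights,
                           f0JitterSd = 0,
                           durationModes = data.frame(
                             minMs = c(30, 50), maxMs = c(50, 300),
                             prob = c(0.5, 0.5)),
                           amDepth = 0) {
  new("SpeciesProfile", name = name, f0Range = as.numeric(f0Range),
      harmonicWeights = as.numeric(harmonicWeights),
      f0JitterSd = as.numeric(f0JitterSd), durationModes = durationModes,
      amDepth = as.numeric(amDepth))
}

#' Built-in species presets
#'
#' Returns the generative profile for one of the built-in species presets.
#' `b_oleae` uses the olive fruit fly's observed 170-210 Hz fundamental band;
#' `a_mellifera` (honey bee) the observed 140-150 Hz band with strong,
#' partially overlapping harmonics. The remaining presets are modelling
#' choices, not field measurements: `mosquito` is a high-pitched 400-650 Hz
#' profile with rapidly decaying harmonics (an easy, well-separated
#' non-target); `chironomidae` shares the b_oleae fundamental band but
#' redistributes power across harmonics (a partially resembling non-target);
#' `l_aristella` is spectrally identical to `b_oleae` (the worst-case,
#' fully overlapping non-target).
#'
#' @param name one of `"b_oleae"`, `"mosquito"`, `"a_mellifera"`,
#'   `"chironomidae"`, `"l_aristella"`.
#' @return a [SpeciesProfile].
#' @examples
#' speciesPreset("b_oleae")
#' @export
speciesPreset <- function(name = c("b_oleae", "mosquito", "a_mellifera",
                                   "chironomidae", "l_aristella")) {
  name <- match.arg(name)
  switch(name,
    b_oleae = speciesProfile("b_oleae", c(170, 210),
                             c(1, 0.65, 0.40, 0.25, 0.12),
                             f0JitterSd = 2.5, amDepth = 0.2),
    mosquito = speciesProfile("mosquito", c(400, 650),
                              c(1, 0.30, 0.10),
                              f0JitterSd = 5, amDepth = 0.2),
    a_mellifera = speciesProfile("a_mellifera", c(140, 150),
                                 c(1, 0.75, 0.50, 0.30, 0.18),
                                 f0JitterSd = 1.5, amDepth = 0.2),
    chironomidae = speciesProfile("chironomidae", c(170, 210),
                                  c(1, 0.15, 0.70, 0.10, 0.45),
                                  f0JitterSd = 2.5, amDepth = 0.2),
    l_aristella = speciesProfile("l_aristella", c(170, 210),
                                 c(1, 0.65, 0.40, 0.25, 0.12),
                                 f0JitterSd = 2.5, amDepth = 0.2)
  )
}

# Raised-cosine onset/offset envelope, ramps of 10% of the event duration.
raisedCosineEnvelope <- function(n) {
  env <- rep(1, n)
  ramp <- max(1L, floor(0.1 * n))
  if (2L * ramp >= n) ramp <- floor(n / 2)
  if (ramp >= 1L) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / (ramp + 1)))
    env[seq_len(ramp)] <- up
    env[n + 1L - seq_len(ramp)] <- up
  }
  env
}

#' Synthesize one wingbeat event
#'
#' Draws a fundamental frequency uniformly from the profile's band, builds the
#' harmonic sum `sum_h w_h sin(h * phi(t) + phase_h)` with slow frequency
#' drift (integrated instantaneous frequency), applies a raised-cosine
#' onset/offset envelope (10% ramps) and optional slow amplitude modulation,
#' peak-normalizes, then adds white Gaussian noise. Identical seeds give
#' identical events.
#'
#' @param profile a [SpeciesProfile].
#' @param durationMs event duration, ms (> 0).
#' @param fs sampling rate, Hz (default 4000).
#' @param noiseSd SD of additive white Gaussian noise (default 0.01,
#'   roughly 30 dB below a full-scale event — the very-high-SNR regime the
#'   optical sensor operates in).
#' @param seed integer for reproducibility, or NULL.
#' @return a [WingbeatEvent] with `f0True` set to the drawn fundamental.
#' @examples
#' ev <- synthEvent(speciesPreset("b_oleae"), 128, seed = 7)
#' range(ev@samples)
#' @export
synthEvent <- function(profile, durationMs, fs = 4000, noiseSd = 0.01,
                       seed = NULL) {
  stopInvalid(!is(profile, "SpeciesProfile"), "profile must be a SpeciesProfile")
  validObject(profile)
  stopInvalid(!is.numeric(fs) || length(fs) != 1L || fs <= 0,
              "fs must be a single positive number")
  stopInvalid(!is.numeric(durationMs) || length(durationMs) != 1L ||
                durationMs <= 0, "durationMs must be a single positive number")
  stopInvalid(noiseSd < 0, "noiseSd must be >= 0")
  n <- max(1L, as.integer(round(durationMs / 1000 * fs)))
  H <- length(profile@harmonicWeights)
  draws <- withSeed(seed, list(
    f0 = runif(1, profile@f0Range[1], profile@f0Range[2]),
    phases = runif(H, 0, 2 * pi),
    driftFreq = runif(1, 0.5, 3),
    driftPhase = runif(1, 0, 2 * pi),
    amFreq = runif(1, 5, 15),
    amPhase = runif(1, 0, 2 * pi),
    noise = rnorm(n, 0, noiseSd)
  ))
  tt <- (seq_len(n) - 1) / fs
  f0Inst <- draws$f0 +
    profile@f0JitterSd * sin(2 * pi * draws$driftFreq * tt + draws$driftPhase)
  phi <- 2 * pi * cumsum(f0Inst) / fs
  x <- numeric(n)
  for (h in seq_len(H)) {
    w <- profile@harmonicWeights[h]
    if (w > 0) x <- x + w * sin(h * phi + draws$phases[h])
  }
  x <- x * raisedCosineEnvelope(n)
  if (profile@amDepth > 0)
    x <- x * (1 - profile@amDepth *
                (0.5 + 0.5 * cos(2 * pi * draws$amFreq * tt + draws$amPhase)))
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  x <- x + draws$noise
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  new("WingbeatEvent", samples = x, fs = fs, species = profile@name,
      f0True = draws$f0)
}

#' Synthesize a sensor stream of labeled events
#'
#' Concatenates silence gaps and wingbeat events drawn from the given
#' profiles (species chosen uniformly per event unless `profileSequence` is
#' given; duration drawn from the profile's flight-mode mixture) into one
#' sample stream, and returns the exact ground-truth log. Gaussian noise with
#' SD `noiseSd` is added across the whole stream, gaps included. The default
#' gap range keeps passes well separated (always at least one silent frame
#' between events at the 512-sample/4 kHz defaults), as they are in the
#' field, where a trap records tens of events per day.
#'
#' @param profiles list of [SpeciesProfile]s.
#' @param nEvents number of events (>= 0).
#' @param gapMsRange numeric(2), uniform range for inter-event gaps, ms.
#' @param fs sampling rate, Hz.
#' @param noiseSd stream-wide additive noise SD.
#' @param seed integer for reproducibility, or NULL.
#' @param profileSequence optional integer vector of length `nEvents` giving
#'   the profile index of each event, for streams of exact composition.
#' @return list with `samples` (numeric stream) and `log` (data.frame with
#'   columns `onset_sample` (1-based), `duration_ms`, `species`, `f0_true`).
#' @examples
#' st <- synthStream(list(speciesPreset("b_oleae")), nEvents = 3, seed = 1)
#' st$log
#' @export
synthStream <- function(profiles, nEvents, gapMsRange = c(400, 1200),
                        fs = 4000, noiseSd = 0.01, seed = NULL,
                        profileSequence = NULL) {
  stopInvalid(nEvents < 0, "nEvents must be >= 0")
  stopInvalid(nEvents > 0 && length(profiles) == 0,
              "profiles must be non-empty when nEvents > 0")
  stopInvalid(!is.null(profileSequence) &&
                (length(profileSequence) != nEvents ||
                   any(profileSequence < 1) ||
                   any(profileSequence > length(profiles))),
              "profileSequence must hold nEvents valid profile indices")
  withSeed(seed, {
    pieces <- list()
    log <- data.frame(onset_sample = integer(), duration_ms = numeric(),
                      species = character(), f0_true = numeric())
    pos <- 0L
    gap0 <- as.integer(round(runif(1, gapMsRange[1], gapMsRange[2]) / 1000 * fs))
    pieces[[1]] <- numeric(gap0)
    pos <- gap0
    for (i in seq_len(nEvents)) {
      prof <- if (is.null(profileSequence)) profiles[[sample.int(length(profiles), 1)]]
              else profiles[[profileSequence[i]]]
      dm <- prof@durationModes
      mode <- sample.int(nrow(dm), 1, prob = dm$prob)
      dur <- runif(1, dm$minMs[mode], dm$maxMs[mode])
      ev <- synthEvent(prof, dur, fs = fs, noiseSd = 0,
                       seed = sample.int(.Machine$integer.max, 1))
      log <- rbind(log, data.frame(
        onset_sample = pos + 1L, duration_ms = dur,
        species = prof@name, f0_true = ev@f0True))
      pieces[[length(pieces) + 1L]] <- ev@samples
      pos <- pos + length(ev@samples)
      gap <- as.integer(round(runif(1, gapMsRange[1], gapMsRange[2]) / 1000 * fs))
      pieces[[length(pieces) + 1L]] <- numeric(gap)
      pos <- pos + gap
    }
    stream <- unlist(pieces, use.names = FALSE)
    if (length(stream) == 0L) stream <- numeric(as.integer(fs))
    if (noiseSd > 0) stream <- stream + rnorm(length(stream), 0, noiseSd)
    list(samples = stream, log = log)
  })
}

#' Synthesize a reference set of whole-event signatures
#'
#' Emulates how a species' reference spectra are collected in the laboratory:
#' each recording is one complete pass through a bench sensor (duration drawn
#' from the profile's flight-mode mixture), featurized in isolation with
#' [eventToSignature()]. Codebooks are normally trained on such a set; the
#' trap then compares its triggered-frame signatures against them.
#'
#' @param profile a [SpeciesProfile].
#' @param n number of recordings (the trap's own reference set used 403).
#' @param fs sampling rate, Hz.
#' @param noiseSd per-event additive noise SD.
#' @param seed integer RNG seed.
#' @param nFft,dcCutBins see [magnitudeSpectrum()].
#' @return a [SpectrumSet] with `species`, `f0_true` and `duration_ms` in its
#'   event metadata.
#' @examples
#' ref <- synthSignatures(speciesPreset("b_oleae"), n = 20, seed = 1)
#' @export
synthSignatures <- function(profile, n, fs = 4000, noiseSd = 0.01, seed = NULL,
                            nFft = 512L, dcCutBins = 3L) {
  stopInvalid(n < 1, "n must be >= 1")
  withSeed(seed, {
    dm <- profile@durationModes
    sigs <- matrix(0, n, nFft / 2)
    meta <- data.frame(species = character(n), f0_true = numeric(n),
                       duration_ms = numeric(n))
    for (i in seq_len(n)) {
      mode <- sample.int(nrow(dm), 1, prob = dm$prob)
      dur <- runif(1, dm$minMs[mode], dm$maxMs[mode])
      ev <- synthEvent(profile, dur, fs = fs, noiseSd = noiseSd,
                       seed = sample.int(.Machine$integer.max, 1))
      sigs[i, ] <- eventToSignature(ev@samples, nFft = nFft,
                                    dcCutBins = dcCutBins)
      meta$species[i] <- profile@name
      meta$f0_true[i] <- ev@f0True
      meta$duration_ms[i] <- dur
    }
    SpectrumSet(sigs, fs = fs, nFft = nFft, eventData = meta)
  })
}

#' Uniform mid-rise quantization round-trip
#'
#' Maps amplitudes in [-1, 1] (values outside are clipped) uniformly onto
#' `2^bits` codes and back to amplitude, emulating the trap's ADC. The
#' mapping is mid-rise: code `k` represents the amplitude
#' `(k + 0.5) * 2 / 2^bits - 1`, so -1 maps to code 0 and +1 to the top code.
#' Idempotent: re-quantizing a quantized signal returns it unchanged.
#'
#' @param samples numeric amplitude sequence.
#' @param bits ADC resolution (>= 2; default 10 as in the trap hardware).
#' @return numeric sequence of dequantized amplitudes, with attribute
#'   `"codes"` holding the integer ADC codes in 0..2^bits-1.
#' @examples
#' quantize(c(-1, 0, 1), bits = 10)
#' @export
quantize <- function(samples, bits = 10) {
  stopInvalid(!is.numeric(bits) || length(bits) != 1L || bits < 2,
              "bits must be a single integer >= 2")
  levels <- 2^as.integer(bits)
  x <- pmax(-1, pmin(1, samples))
  codes <- pmin(levels - 1, floor((x + 1) / 2 * levels))
  out <- (codes + 0.5) * 2 / levels - 1
  attr(out, "codes") <- as.integer(codes)
  out
}

#' @describeIn WingbeatEvent-class display summary
#' @param object a WingbeatEvent
#' @export
setMethod("show", "WingbeatEvent", function(object) {
  cat(sprintf("WingbeatEvent: %d samples @ %g Hz (%.1f ms)\n",
              length(object@samples), object@fs,
              1000 * length(object@samples) / object@fs))
  if (!is.na(object@species)) cat("  species:", object@species, "\n")
  if (!is.na(object@f0True)) cat(sprintf("  f0 (true): %.2f Hz\n", object@f0True))
})

#' @describeIn SpeciesProfile-class display summary
#' @param object a SpeciesProfile
#' @export
setMethod("show", "SpeciesProfile", function(object) {
  cat(sprintf("SpeciesProfile '%s': f0 in [%g, %g] Hz, %d harmonics, jitter %g Hz, AM depth %g\n",
              object@name, object@f0Range[1], object@f0Range[2],
              length(object@harmonicWeights), object@f0JitterSd, object@amDepth))
})
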