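#' Extract the signature matrix
#'
#' Returns the events-by-bins matrix of normalized magnitude spectra
#' (one row per event, `nFft/2` columns).
#'
#' @param x a [SpectrumSet].
#' @return numeric matrix, rows = events, columns = frequency bins.
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' Extract codebook prototypes
#'
#' @param x a [Codebook].
#' @return numeric matrix, K rows (unit-norm prototype spectra) by nBins.
#' @export
setGeneric("prototypes", function(x) standardGeneric("prototypes"))

#' Extract the acceptance threshold
#'
#' @param x a calibrated [Codebook].
#' @return numeric, the mean + 3 SD acceptance threshold on minimum L1
#'   distance (NA if the codebook is uncalibrated).
#' @export
setGeneric("acceptanceThreshold", function(x) standardGeneric("acceptanceThreshold"))

#' Minimum L1 distance to a codebook
#'
#' Computes, for each spectrum, the minimum over prototypes of the absolute
#' (L1) distance `sum(|s_i - p_i|)` — the trap firmware's similarity measure.
#'
#' @param s a numeric signature vector, an events-by-bins matrix, or a
#'   [SpectrumSet].
#' @param codebook a [Codebook].
#' @return numeric vector of minimum distances, one per spectrum.
#' @export
setGeneric("minDistance", function(s, codebook) standardGeneric("minDistance"))

#' Open-set verification against a codebook
#'
#' Declares a spectrum a `target` when its minimum L1 distance to the
#' codebook prototypes does not exceed the calibrated mean + 3 SD threshold,
#' else `non_target`. A distance exactly equal to the threshold is accepted
#' (only distances *more than* the threshold are rejected).
#'
#' @param s a numeric signature vector, an events-by-bins matrix, or a
#'   [SpectrumSet].
#' @param codebook a calibrated [Codebook].
#' @return data.frame with columns `distance` and `decision`
#'   (`"target"`/`"non_target"`), one row per spectrum.
#' @export
setGeneric("verify", function(s, codebook) standardGeneric("verify"))

#' Two-codebook closed-set classification
#'
#' Assigns each spectrum the species of the codebook with the smaller minimum
#' L1 distance. Ties go to `bookA` with a warning.
#'
#' @param s a numeric signature vector, an events-by-bins matrix, or a
#'   [SpectrumSet].
#' @param bookA,bookB calibrated [Codebook]s over the same bin grid.
#' @return data.frame with columns `label`, `distA`, `distB`.
#' @export
setGeneric("classifyTwoCodebooks", function(s, bookA, bookB)
  standardGeneric("classifyTwoCodebooks"))
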