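# Independent oracles and shared fixtures, all built in code.

# Naive O(N^2) DFT: magnitudes of the first n/2 bins.
naiveDftMagnitudes <- function(x) {
  n <- length(x)
  k <- seq_len(n / 2) - 1
  vapply(k, function(kk) {
    ang <- -2 * pi * kk * (seq_len(n) - 1) / n
    Mod(complex(real = sum(x * cos(ang)), imaginary = sum(x * sin(ang))))
  }, numeric(1))
}

# Reference magnitude-spectrum path built only from the naive DFT
# (window coefficients recomputed from the published formula, not reused).
oracleMagnitudeSpectrum <- function(frame, nFft = 512, dcCutBins = 3) {
  n <- length(frame)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / n)
  x <- c(frame * w, numeric(nFft - n))
  mags <- naiveDftMagnitudes(x)
  if (dcCutBins > 0) mags[seq_len(dcCutBins)] <- 0
  mags
}

# Exhaustive-assignment Lloyd iteration from given initial centers.
bruteLloyd <- function(x, centers, iterMax = 100) {
  assign <- NULL
  for (it in seq_len(iterMax)) {
    d <- sapply(seq_len(nrow(centers)), function(k)
      colSums((t(x) - centers[k, ])^2))
    assign <- max.col(-d, ties.method = "first")
    newc <- centers
    for (k in seq_len(nrow(centers)))
      if (any(assign == k))
        newc[k, ] <- colMeans(x[assign == k, , drop = FALSE])
    if (max(abs(newc - centers)) < 1e-12) break
    centers <- newc
  }
  list(centers = centers, cluster = assign)
}

# A pure sinusoid landing exactly on FFT bin `bin`.
sineFrame <- function(bin, n = 512, amp = 1, phase = 0) {
  amp * sin(2 * pi * bin * (seq_len(n) - 1) / n + phase)
}

# Single-harmonic, drift-free, unmodulated profile over a species' f0 band.
pureToneProfile <- function(f0Range, name = "tone") {
  speciesProfile(name, f0Range, 1, f0JitterSd = 0, amDepth = 0)
}

# Shared B. oleae reference codebook (computed once per test run).
.fixtures <- new.env(parent = emptyenv())
refBOleaeCodebook <- function() {
  if (is.null(.fixtures$bk)) {
    ref <- synthSignatures(speciesPreset("b_oleae"), 403, seed = 11)
    .fixtures$bk <- learnCodebook(ref, k = 4, seed = 1)
    .fixtures$ref <- ref
  }
  .fixtures$bk
}
refBOleaeSignatures <- function() {
  refBOleaeCodebook()
  .fixtures$ref
}
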