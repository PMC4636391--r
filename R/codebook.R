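asSpectrumMatrix <- function(s) {
  if (is(s, "SpectrumSet")) spectra(s)
  else if (is.matrix(s)) s
  else matrix(s, nrow = 1)
}

#' Seeded farthest-point (k-means++ style) initial centers
#'
#' Picks the first center uniformly at random, then each subsequent center
#' with probability proportional to the squared Euclidean distance to the
#' nearest center already chosen.
#'
#' @param x numeric matrix, rows = observations.
#' @param k number of centers.
#' @param seed integer RNG seed, or NULL.
#' @return numeric matrix of k rows drawn from `x`.
#' @export
kmeansppCenters <- function(x, k, seed = NULL) {
  withSeed(seed, {
    n <- nrow(x)
    idx <- integer(k)
    idx[1] <- sample.int(n, 1)
    d2 <- colSums((t(x) - x[idx[1], ])^2)
    for (j in seq_len(k - 1)) {
      if (all(d2 == 0)) idx[j + 1] <- sample.int(n, 1)
      else idx[j + 1] <- sample.int(n, 1, prob = d2)
      d2 <- pmin(d2, colSums((t(x) - x[idx[j + 1], ])^2))
    }
    x[idx, , drop = FALSE]
  })
}

#' Mean + 3 SD acceptance threshold from a set of distances
#'
#' The open-set calibration statistic: the expected maximum divergence of the
#' target species from its prototypes is taken as the mean of the training
#' minimum distances enlarged by three standard deviations (sample, n-1
#' denominator).
#'
#' @param d numeric vector of >= 2 distances.
#' @return list with `muD`, `sigmaD` and `threshold = muD + 3 * sigmaD`.
#' @examples
#' thresholdFromDistances(c(0, 1, 2, 3))$threshold
#' @export
thresholdFromDistances <- function(d) {
  stopInvalid(length(d) < 2, "need at least 2 distances")
  muD <- mean(d)
  sigmaD <- sd(d)
  list(muD = muD, sigmaD = sigmaD, threshold = muD + 3 * sigmaD)
}

#' Calibrate the acceptance threshold of a prototype set
#'
#' Computes the minimum L1 distance of every training spectrum to the
#' prototypes and returns the mean, sample SD and mean + 3 SD threshold of
#' those distances.
#'
#' @param spectra training spectra: [SpectrumSet] or events-by-bins matrix
#'   with >= 2 rows.
#' @param prototypes numeric matrix, K rows of unit-norm prototypes.
#' @return list with `muD`, `sigmaD`, `threshold` and the per-spectrum
#'   `distances`.
#' @export
calibrateThreshold <- function(spectra, prototypes) {
  m <- asSpectrumMatrix(spectra)
  stopInvalid(nrow(m) < 2, "need at least 2 training spectra")
  d <- minDistanceMatrix(m, prototypes)
  c(thresholdFromDistances(d), list(distances = d))
}

minDistanceMatrix <- function(m, prot) {
  stopInvalid(ncol(m) != ncol(prot), "spectrum/prototype length mismatch")
  vapply(seq_len(nrow(m)), function(i) {
    min(rowSums(abs(sweep(prot, 2, m[i, ]))))
  }, numeric(1))
}

#' Learn a species codebook by K-means clustering
#'
#' Partitions the training signatures into K groups with Lloyd's K-means
#' (Euclidean objective, seeded k-means++ initialization, `nstart` restarts,
#' best within-cluster sum of squares kept), re-normalizes the centroids to
#' unit L2 norm so the prototypes live in signature space, and calibrates the
#' mean + 3 SD acceptance threshold on the same training spectra.
#'
#' @param spectra training spectra: [SpectrumSet] or events-by-bins matrix.
#' @param k number of prototypes (default 4, as stored in the trap's EEPROM).
#' @param seed integer RNG seed for the clustering restarts.
#' @param species label stored in the codebook (defaults to the most common
#'   `species` in the SpectrumSet metadata, else `"target"`).
#' @param nstart number of seeded restarts (default 10).
#' @param iterMax Lloyd iteration cap per restart (default 100).
#' @return a calibrated [Codebook].
#' @examples
#' evs <- t(sapply(1:30, function(i)
#'   eventToSignature(synthEvent(speciesPreset("b_oleae"), 128, seed = i)@samples)))
#' learnCodebook(evs, k = 4, seed = 1)
#' @export
learnCodebook <- function(spectra, k = 4L, seed = 1L, species = NULL,
                          nstart = 10L, iterMax = 100L) {
  m <- asSpectrumMatrix(spectra)
  stopInvalid(nrow(m) < k, "need at least k training spectra")
  if (is.null(species)) {
    species <- "target"
    if (is(spectra, "SpectrumSet")) {
      cd <- SummarizedExperiment::colData(spectra)
      if ("species" %in% names(cd))
        species <- names(sort(table(cd$species), decreasing = TRUE))[1]
    }
  }
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nstart)) {
      centers <- kmeansppCenters(m, k, seed = NULL)
      km <- tryCatch(
        suppressWarnings(kmeans(m, centers = centers, iter.max = iterMax,
                                algorithm = "Lloyd")),
        error = function(e) NULL)  # e.g. an empty cluster in this restart
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss)) best <- km
    }
  })
  stopInvalid(is.null(best), "k-means failed in every restart")
  prot <- best$centers
  nrm <- sqrt(rowSums(prot^2))
  stopInvalid(any(nrm == 0), "degenerate all-zero centroid")
  prot <- prot / nrm
  dimnames(prot) <- NULL
  cal <- calibrateThreshold(m, prot)
  new("Codebook", species = species, prototypes = prot,
      muD = cal$muD, sigmaD = cal$sigmaD, threshold = cal$threshold,
      nTrain = nrow(m), seed = as.integer(seed))
}

#' @rdname prototypes
#' @export
setMethod("prototypes", "Codebook", function(x) x@prototypes)

#' @rdname acceptanceThreshold
#' @export
setMethod("acceptanceThreshold", "Codebook", function(x) x@threshold)

#' @rdname minDistance
#' @export
setMethod("minDistance", signature("numeric", "Codebook"), function(s, codebook) {
  minDistanceMatrix(matrix(s, nrow = 1), codebook@prototypes)
})

#' @rdname minDistance
#' @export
setMethod("minDistance", signature("matrix", "Codebook"), function(s, codebook) {
  minDistanceMatrix(s, codebook@prototypes)
})

#' @rdname minDistance
#' @export
setMethod("minDistance", signature("SpectrumSet", "Codebook"), function(s, codebook) {
  minDistanceMatrix(spectra(s), codebook@prototypes)
})

verifyCore <- function(s, codebook) {
  stopInvalid(is.na(codebook@threshold),
              "codebook is not calibrated (threshold is NA)")
  d <- minDistance(s, codebook)
  data.frame(distance = d,
             decision = ifelse(d <= codebook@threshold, "target", "non_target"))
}

#' @rdname verify
#' @export
setMethod("verify", signature("numeric", "Codebook"), verifyCore)
#' @rdname verify
#' @export
setMethod("verify", signature("matrix", "Codebook"), verifyCore)
#' @rdname verify
#' @export
setMethod("verify", signature("SpectrumSet", "Codebook"), verifyCore)

classifyCore <- function(s, bookA, bookB) {
  stopInvalid(ncol(bookA@prototypes) != ncol(bookB@prototypes),
              "codebooks have different spectrum lengths")
  dA <- minDistance(s, bookA)
  dB <- minDistance(s, bookB)
  if (any(dA == dB))
    warning(sum(dA == dB), " tie(s) broken toward '", bookA@species, "'")
  data.frame(label = ifelse(dA <= dB, bookA@species, bookB@species),
             distA = dA, distB = dB)
}

#' @rdname classifyTwoCodebooks
#' @export
setMethod("classifyTwoCodebooks", signature("numeric", "Codebook", "Codebook"),
          classifyCore)
#' @rdname classifyTwoCodebooks
#' @export
setMethod("classifyTwoCodebooks", signature("matrix", "Codebook", "Codebook"),
          classifyCore)
#' @rdname classifyTwoCodebooks
#' @export
setMethod("classifyTwoCodebooks", signature("SpectrumSet", "Codebook", "Codebook"),
          classifyCore)

#' @describeIn Codebook-class display summary
#' @param object a Codebook
#' @export
setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook '%s': K=%d prototypes of %d bins, trained on %d spectra\n",
              object@species, nrow(object@prototypes),
              ncol(object@prototypes), object@nTrain))
  if (!is.na(object@threshold))
    cat(sprintf("  distance stats: mu=%.4f sd=%.4f threshold (mu+3sd)=%.4f\n",
                object@muD, object@sigmaD, object@threshold))
  else cat("  uncalibrated\n")
})

#' Serialize / deserialize a codebook as JSON
#'
#' @param codebook a [Codebook].
#' @param path file path.
#' @param maxPrototypes optional cap on K; `writeCodebook` errors when K
#'   exceeds it. Use 6 to emulate the trap's EEPROM capacity
#'   (embedded-profile mode); the library itself imposes no limit.
#' @return `writeCodebook` returns `path` invisibly; `readCodebook` a
#'   [Codebook].
#' @export
writeCodebook <- function(codebook, path, maxPrototypes = NULL) {
  if (!is.null(maxPrototypes))
    stopInvalid(nrow(codebook@prototypes) > maxPrototypes,
                sprintf("codebook has %d prototypes; embedded profile allows %d",
                        nrow(codebook@prototypes), maxPrototypes))
  obj <- list(species = codebook@species, k = nrow(codebook@prototypes),
              prototypes = codebook@prototypes, mu_d = codebook@muD,
              sigma_d = codebook@sigmaD, threshold = codebook@threshold,
              n_train = codebook@nTrain, seed = codebook@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCodebook
#' @export
readCodebook <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("Codebook", species = obj$species,
      prototypes = matrix(obj$prototypes, nrow = obj$k),
      muD = obj$mu_d, sigmaD = obj$sigma_d, threshold = obj$threshold,
      nTrain = as.integer(obj$n_train), seed = as.integer(obj$seed))
}
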