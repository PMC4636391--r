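# Four distinct unit-norm spectra used as degenerate cluster centers.
fourTones <- function() {
  t(sapply(c(23, 50, 90, 140), function(b)
    normalizeSpectrum(magnitudeSpectrum(sineFrame(b), dcCutBins = 0))))
}

test_that("degenerate repeated-spectrum training recovers the spectra exactly", {
  base <- fourTones()
  train <- base[rep(1:4, each = 50), ]
  bk <- learnCodebook(train, k = 4, seed = 2)
  # prototypes equal the four distinct spectra, in some order
  ord <- apply(prototypes(bk), 1, function(p)
    which.min(rowSums(abs(sweep(base, 2, p)))))
  expect_setequal(ord, 1:4)
  expect_lt(max(abs(prototypes(bk)[order(ord), ] - base)), 1e-9)
  expect_equal(bk@muD, 0, tolerance = 1e-9)
  expect_equal(bk@sigmaD, 0, tolerance = 1e-9)
  expect_equal(acceptanceThreshold(bk), 0, tolerance = 1e-9)
  # every training spectrum verifies as target (distance 0 <= threshold 0)
  expect_true(all(verify(train, bk)$decision == "target"))
  expect_error(learnCodebook(base, k = 5, seed = 1), "at least k")
})

test_that("clustering matches a brute-force Lloyd oracle on separated clusters", {
  set.seed(4)
  a <- synthSignatures(pureToneProfile(c(180, 190)), 20, noiseSd = 0, seed = 5)
  b <- synthSignatures(pureToneProfile(c(500, 520)), 20, noiseSd = 0, seed = 6)
  x <- rbind(spectra(a), spectra(b))
  bk <- learnCodebook(x, k = 2, seed = 9)
  # oracle: exhaustive-assignment Lloyd from the same seeded initialization
  oracle <- bruteLloyd(x, kmeansppCenters(x, 2, seed = 9))
  oc <- oracle$centers / sqrt(rowSums(oracle$centers^2))
  perm <- if (sum(abs(prototypes(bk)[1, ] - oc[1, ])) <
              sum(abs(prototypes(bk)[1, ] - oc[2, ]))) 1:2 else 2:1
  expect_lt(max(abs(prototypes(bk) - oc[perm, ])), 1e-8)
  # and the centroids are the per-cluster label means (independent route)
  mu <- rbind(colMeans(x[1:20, ]), colMeans(x[21:40, ]))
  mu <- mu / sqrt(rowSums(mu^2))
  perm2 <- if (sum(abs(prototypes(bk)[1, ] - mu[1, ])) <
               sum(abs(prototypes(bk)[1, ] - mu[2, ]))) 1:2 else 2:1
  expect_lt(max(abs(prototypes(bk) - mu[perm2, ])), 1e-8)
})

test_that("minimum L1 distance matches a brute-force loop", {
  # closed forms
  bk2 <- new("Codebook", species = "toy", prototypes = matrix(c(0, 1), 1))
  expect_equal(minDistance(c(1, 0), bk2), 2)
  expect_equal(minDistance(c(0, 1), bk2), 0)
  expect_error(minDistance(c(1, 0, 0), bk2), "mismatch")
  expect_error(verify(c(1, 0), bk2), "not calibrated")
  # random spectra against 4 random prototypes
  set.seed(12)
  prot <- t(sapply(1:4, function(i) normalizeSpectrum(abs(rnorm(64)))))
  bk <- new("Codebook", species = "r", prototypes = prot)
  for (i in 1:20) {
    s <- normalizeSpectrum(abs(rnorm(64)))
    brute <- min(vapply(1:4, function(k) sum(abs(s - prot[k, ])), numeric(1)))
    expect_equal(minDistance(s, bk), brute)
    # triangle sanity: min distance never exceeds any single-prototype sum
    for (k in 1:4) expect_lte(minDistance(s, bk), sum(abs(s - prot[k, ])))
  }
})

test_that("threshold calibration follows the mean + 3 SD rule", {
  # zero variance: threshold equals the common distance
  expect_equal(thresholdFromDistances(rep(1.7, 10))$threshold, 1.7)
  # hand-computed case with sample (n-1) SD
  cal <- thresholdFromDistances(c(0, 1, 2, 3))
  expect_equal(cal$muD, 1.5)
  expect_equal(cal$sigmaD, sqrt(5 / 3))
  expect_equal(cal$threshold, 5.37298, tolerance = 1e-5)
  expect_error(thresholdFromDistances(1), "at least 2")
  # calibrateThreshold composes min-distance with the same statistic
  prot <- fourTones()
  train <- prot[rep(1:2, each = 5), ]
  cal2 <- calibrateThreshold(train, prot)
  expect_equal(cal2$threshold, 0, tolerance = 1e-12)
  expect_equal(length(cal2$distances), 10L)
})

test_that("verification boundary accepts distances equal to the threshold", {
  prot <- fourTones()
  bk <- new("Codebook", species = "t", prototypes = prot,
            muD = 0, sigmaD = 0, threshold = 0, nTrain = 4L, seed = 1L)
  expect_equal(verify(prot[1, ], bk)$decision, "target")   # distance == 0
  other <- normalizeSpectrum(magnitudeSpectrum(sineFrame(200), dcCutBins = 0))
  expect_equal(verify(other, bk)$decision, "non_target")   # distance > 0
})

test_that("codebook learning is seed-stable and its invariants hold", {
  ss <- synthSignatures(speciesPreset("b_oleae"), 60, seed = 14)
  b1 <- learnCodebook(ss, k = 4, seed = 31)
  b2 <- learnCodebook(ss, k = 4, seed = 31)
  expect_identical(prototypes(b1), prototypes(b2))
  expect_identical(acceptanceThreshold(b1), acceptanceThreshold(b2))
  expect_equal(acceptanceThreshold(b1), b1@muD + 3 * b1@sigmaD)
  expect_true(all(abs(sqrt(rowSums(prototypes(b1)^2)) - 1) < 1e-6))
  expect_equal(b1@nTrain, 60L)
  expect_equal(b1@species, "b_oleae")   # taken from event metadata
})

test_that("training spectra self-verify as target at high rate", {
  bk <- refBOleaeCodebook()
  dec <- verify(refBOleaeSignatures(), bk)$decision
  expect_gte(mean(dec == "target"), 0.99)
})

test_that("foreign species are rejected, increasingly so with band distance", {
  bk <- refBOleaeCodebook()
  # mosquito-preset signatures against the B. oleae codebook
  mos <- synthSignatures(speciesPreset("mosquito"), 200, seed = 5)
  expect_gte(mean(verify(mos, bk)$decision == "non_target"), 0.95)
  # open-set sweep: non-target rate is non-decreasing as f0 moves away
  bands <- list(c(170, 210), c(220, 260), c(270, 310), c(330, 370),
                c(400, 650))
  rates <- vapply(seq_along(bands), function(i) {
    p <- speciesProfile("foreign", bands[[i]], c(1, 0.3, 0.1),
                        f0JitterSd = 2.5, amDepth = 0.2)
    s <- synthSignatures(p, 60, seed = 60 + i)
    mean(verify(s, bk)$decision == "non_target")
  }, numeric(1))
  expect_true(all(diff(rates) >= -1e-12))
})

test_that("two-codebook classification picks the nearer codebook", {
  bkA <- new("Codebook", species = "a", prototypes = matrix(c(1, 0), 1),
             muD = 0, sigmaD = 0, threshold = 0, nTrain = 1L, seed = 1L)
  bkB <- new("Codebook", species = "b", prototypes = matrix(c(0, 1), 1),
             muD = 0, sigmaD = 0, threshold = 0, nTrain = 1L, seed = 1L)
  r <- classifyTwoCodebooks(c(1, 0), bkA, bkB)
  expect_equal(r$label, "a")
  expect_equal(c(r$distA, r$distB), c(0, 2))
  # tie goes to book A, with a warning
  expect_warning(rt <- classifyTwoCodebooks(normalizeSpectrum(c(1, 1)),
                                            bkA, bkB), "tie")
  expect_equal(rt$label, "a")
})

test_that("codebooks serialize to JSON and honor the embedded K cap", {
  bk <- refBOleaeCodebook()
  path <- tempfile(fileext = ".json")
  writeCodebook(bk, path)
  back <- readCodebook(path)
  expect_equal(prototypes(back), prototypes(bk), tolerance = 1e-12)
  expect_equal(acceptanceThreshold(back), acceptanceThreshold(bk))
  expect_equal(back@species, bk@species)
  expect_silent(writeCodebook(bk, path, maxPrototypes = 6))
  expect_error(writeCodebook(bk, path, maxPrototypes = 3), "embedded")
})
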