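test_that("TIC normalization scales to unit sum and is idempotent", {
  sp <- list(mz = 1:3, intensity = c(2, 3, 5))
  n1 <- ticNormalize(sp)
  expect_equal(n1$intensity, c(0.2, 0.3, 0.5))
  expect_equal(ticNormalize(n1), n1)
  expect_error(ticNormalize(list(mz = 1:3, intensity = c(0, 0, 0))),
               "no positive intensity")
})

test_that("binning follows the half-open 0.020 Da grid with weighted centroids", {
  b <- binCentroids(list(mz = c(200.003, 200.015), intensity = c(1, 3)),
                    binWidth = 0.020, range = c(200, 600))
  expect_equal(nrow(b), 1L)
  expect_equal(b$intensity, 4)
  expect_equal(b$mz, (1 * 200.003 + 3 * 200.015) / 4)
  # single point: centroid is that m/z
  b <- binCentroids(list(mz = 321.4567, intensity = 2), range = c(200, 600))
  expect_equal(b$mz, 321.4567)
  # a point exactly on a bin edge belongs to the upper bin
  b <- binCentroids(list(mz = c(200.0199999, 200.02), intensity = c(1, 1)),
                    binWidth = 0.020, range = c(200, 600))
  expect_equal(b$bin, c(0L, 1L))
})

test_that("binning conserves total intensity exactly and matches brute force", {
  bruteForce <- function(mz, intensity, w, lo) {
    bins <- unique(floor((mz - lo) / w))
    out <- NULL
    for (bn in sort(bins)) {
      member <- mz >= lo + bn * w & mz < lo + (bn + 1) * w
      tot <- sum(intensity[member])
      ctr <- if (tot > 0) sum(mz[member] * intensity[member]) / tot
             else mean(mz[member])
      out <- rbind(out, data.frame(bin = bn, mz = ctr, intensity = tot))
    }
    out
  }
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(1:100, 1)
    mz <- sort(runif(n, 200, 600))
    intensity <- rpois(n, 4) * 0.5
    got <- binCentroids(list(mz = mz, intensity = intensity),
                        binWidth = 0.020, range = c(200, 600))
    want <- bruteForce(mz, intensity, 0.020, 200)
    expect_equal(got$bin, want$bin)
    expect_equal(got$mz, want$mz)
    expect_equal(got$intensity, want$intensity)
    expect_equal(sum(got$intensity), sum(intensity))
  }
})

test_that("the relative threshold is strict and monotone", {
  pk <- data.frame(intensity = c(1.0, 1.01, 50, 1000))
  kept <- thresholdFilter(pk, referenceMax = 1000, fraction = 0.001)
  expect_equal(kept$intensity, c(1.01, 50, 1000))
  expect_equal(nrow(thresholdFilter(pk, 1000, fraction = 0)), 4L)
  set.seed(8)
  pk <- data.frame(intensity = runif(300))
  counts <- vapply(c(0, 0.001, 0.01, 0.1, 0.5, 1),
                   function(f) nrow(thresholdFilter(pk, 1, f)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("top-K selection caps features with lower-m/z tie-breaking", {
  mkpm <- function(mz, values) {
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(intensity = values),
      rowData = S4Vectors::DataFrame(mz = mz, bin = seq_along(mz)),
      colData = S4Vectors::DataFrame(pixel = seq_len(ncol(values)),
                                     i = 0L, j = 0L))
    new("PeakMatrix", se)
  }
  set.seed(12)
  v <- matrix(runif(800 * 3, 0, 1e-3), 800, 3)
  pm <- mkpm(sort(runif(800, 200, 600)), v)
  expect_equal(nrow(selectTopK(pm, 500L)), 500L)
  expect_equal(nrow(selectTopK(pm, 2000L)), 800L)
  # equal means: the lower m/z wins the last slot
  v2 <- matrix(c(5, 3, 3, 1), 4, 3) * 1e-4
  pm2 <- mkpm(c(300, 310, 320, 330), v2)
  expect_equal(featureMz(selectTopK(pm2, 2L)), c(300, 310))
})

test_that("the feature matrix pipeline composes the published stages", {
  sim <- generateSmear(tinyConfig(seed = 61))
  pm <- buildFeatureMatrix(sim$dataset)
  expect_s4_class(pm, "PeakMatrix")
  expect_lte(nrow(pm), 500L)
  expect_false(anyNA(assay(pm)))
  # TIC scale: per-pixel totals of the kept bins never exceed 1
  expect_true(all(colSums(assay(pm)) <= 1 + 1e-9))
  # the marker bin is present, with its centroid within 0.005 Da of truth
  marker <- sim$truth$panel$mz[sim$truth$panel$isMarker][1]
  d <- abs(featureMz(pm) - marker)
  expect_lt(min(d), 0.005)
})

test_that("the matrix path equals per-spectrum binning plus normalization", {
  sim <- generateSmear(tinyConfig(seed = 62))
  pm <- buildFeatureMatrix(sim$dataset, thresholdFraction = 0, topK = Inf)
  k <- 7L  # arbitrary pixel
  ref <- binCentroids(ticNormalize(getSpectrum(sim$dataset, k)),
                      binWidth = 0.020, range = mzRange(sim$dataset))
  col <- match(k, colData(pm)$pixel)
  got <- assay(pm)[match(ref$bin, rowData(pm)$bin), col]
  expect_equal(unname(got), ref$intensity)
})

test_that("all-zero pixels are excluded and fully empty datasets error", {
  mz <- c(300, 300.005, 450)
  intensity <- cbind(c(1, 2, 3), c(0, 0, 0), c(2, 1, 0), c(1, 1, 1))
  d <- MSIDataset(mz = mz, intensity = intensity, nX = 2, nY = 2)
  pm <- buildFeatureMatrix(d, topK = Inf)
  expect_equal(metadata(pm)$excludedPixels, 2L)
  expect_equal(colData(pm)$pixel, c(1L, 3L, 4L))
  empty <- MSIDataset(mz = mz, intensity = matrix(0, 3, 4), nX = 2, nY = 2)
  expect_error(buildFeatureMatrix(empty), "empty")
})

test_that("neighboring m/z ranges concatenate to the summed feature count", {
  lowCfg <- tinyConfig(seed = 63, mzRange = c(200, 600))
  hiCfg <- tinyConfig(seed = 63, mzRange = c(600, 900))
  a <- buildFeatureMatrix(generateSmear(lowCfg)$dataset, topK = 40L)
  b <- buildFeatureMatrix(generateSmear(hiCfg)$dataset, topK = 40L)
  both <- combinePeakMatrices(a, b)
  expect_equal(nrow(both), nrow(a) + nrow(b))
  expect_false(is.unsorted(featureMz(both), strictly = TRUE))
  expect_error(combinePeakMatrices(a, a[, 1:10]), "different pixel sets")
})
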