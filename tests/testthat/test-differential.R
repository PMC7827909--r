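test_that("the Welch statistic matches a hand-computed oracle", {
  # explicit Welch formulas, independent of stats::t.test
  welchOracle <- function(x, y) {
    vx <- sum((x - mean(x))^2) / (length(x) - 1)
    vy <- sum((y - mean(y))^2) / (length(y) - 1)
    sx <- vx / length(x); sy <- vy / length(y)
    t <- (mean(x) - mean(y)) / sqrt(sx + sy)
    df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
    list(t = t, p = 2 * stats::pt(-abs(t), df))
  }
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  got <- tTestFeature(x, y)
  want <- welchOracle(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$t, -sqrt(6 / 5), tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:10) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), sd = 2)
    got <- tTestFeature(x, y)
    want <- welchOracle(x, y)
    expect_equal(got$t, want$t)
    expect_equal(got$p, want$p)
  }
})

test_that("degenerate groups follow the documented conventions", {
  expect_equal(tTestFeature(c(2, 2, 2), c(2, 2)), list(t = 0, p = 1))
  z <- tTestFeature(c(3, 3), c(1, 1, 1))
  expect_equal(z$t, Inf)
  expect_equal(z$p, 0)
  expect_error(tTestFeature(1, c(1, 2)), "at least 2")
})

test_that("t, p and fold change are invariant under global rescaling", {
  study <- generateStudy(tinyConfig(seed = 81), nDonors = 3L)
  rt <- studyRoiTable(study, topK = 60L)
  d1 <- differentialTable(rt, "RBC")
  rt2 <- rt
  rt2@values <- rt@values * 7.3
  d2 <- differentialTable(rt2, "RBC")
  expect_equal(d2$t, d1$t)
  expect_equal(d2$p, d1$p)
  expect_equal(d2$foldChange, d1$foldChange)
})

test_that("ROI aggregation means member pixels and keeps the design counts", {
  sim <- generateSmear(tinyConfig(seed = 82))
  pm <- buildFeatureMatrix(sim$dataset, topK = 50L)
  rt <- aggregateRois(pm, sim$roiSet, sim$dataset)
  info <- roiInfo(rt)
  expect_equal(as.integer(table(info$label)[c("RBC", "WBC", "plasma")]),
               c(5L, 1L, 3L))
  # a single-pixel ROI equals that pixel's column
  one <- which(info$nPixels == 1L)[1]
  roi <- rois(sim$roiSet)[one, ]
  px <- pixelsInRoi(sim$dataset, roi)
  expect_equal(unname(roiValues(rt)[one, ]),
               unname(assay(pm)[, match(px, colData(pm)$pixel)]))
  # full study: 30 RBC + 6 WBC + 18 plasma rows over 6 donors
  study <- generateStudy(tinyConfig(seed = 83), nDonors = 6L)
  srt <- studyRoiTable(study, topK = 50L)
  expect_equal(as.integer(table(roiInfo(srt)$label)[c("RBC", "WBC",
                                                      "plasma")]),
               c(30L, 6L, 18L))
})

test_that("uniform intensities aggregate to that constant", {
  d <- MSIDataset(mz = c(300, 400), intensity = matrix(1, 2, 16),
                  nX = 4, nY = 4)
  pm <- buildFeatureMatrix(d, topK = Inf)
  rs <- ROISet(label = c("RBC", "plasma"), centerX = c(12, 20),
               centerY = c(10.5, 17.5), semiX = 9, semiY = 8)
  rt <- aggregateRois(pm, rs, d)
  expect_true(all(abs(roiValues(rt) - 0.5) < 1e-12))
})

test_that("empty ROIs are dropped with a warning; all empty is an error", {
  d <- MSIDataset(mz = c(300, 400), intensity = matrix(1, 2, 16),
                  nX = 4, nY = 4)
  pm <- buildFeatureMatrix(d, topK = Inf)
  rs <- ROISet(label = c("RBC", "plasma"), centerX = c(12, 500),
               centerY = c(10.5, 500), semiX = c(9, 0.1), semiY = c(8, 0.1))
  expect_warning(rt <- aggregateRois(pm, rs, d), "dropped")
  expect_equal(nrow(roiInfo(rt)), 1L)
  rsBad <- ROISet(label = "RBC", centerX = 500, centerY = 500,
                  semiX = 0.1, semiY = 0.1)
  expect_warning(expect_error(aggregateRois(pm, rsBad, d), "empty"))
})

test_that("differential tables flag by the significance limit", {
  study <- generateStudy(tinyConfig(seed = 84), nDonors = 6L)
  rt <- studyRoiTable(study)
  dt <- differentialTable(rt, "RBC", alpha = 0)
  expect_equal(sum(dt$significant), 0L)
  dt <- differentialTable(rt, "RBC", alpha = 0.05)
  expect_true(all(dt$significant == (dt$p < 0.05)))
  # the truth-enriched marker is flagged with fold change above 1
  truth <- study$smears[[1]]$truth$enriched
  rbcUp <- truth[truth$cellType == "RBC" & truth$direction > 0, ]
  f <- which.min(abs(dt$mz - rbcUp$mz[1]))
  expect_lt(abs(dt$mz[f] - rbcUp$mz[1]), 0.025)
  expect_true(dt$significant[f])
  expect_gt(dt$foldChange[f], 1)
})

test_that("plasma rows are required", {
  study <- generateStudy(tinyConfig(seed = 85), nDonors = 3L)
  rt <- studyRoiTable(study, topK = 40L)
  keep <- roiInfo(rt)$label != "plasma"
  rt@values <- rt@values[keep, , drop = FALSE]
  rt@roiInfo <- rt@roiInfo[keep, , drop = FALSE]
  expect_error(differentialTable(rt, "RBC"), "plasma")
})

test_that("label permutation under the null preserves the flagged rate", {
  study <- generateStudy(calibConfig(seed = 86), nDonors = 6L)
  rt <- studyRoiTable(study)
  lab <- roiInfo(rt)$label
  rows <- lab != "WBC"
  baseRate <- mean(differentialTable(rt, "RBC")$significant)
  set.seed(5)
  rates <- vapply(1:10, function(i) {
    perm <- rt
    perm@roiInfo$label[rows] <- sample(lab[rows])
    mean(differentialTable(perm, "RBC")$significant)
  }, numeric(1))
  # permuted null rates scatter around alpha like the observed one
  expect_lt(abs(mean(rates) - 0.05), 0.03)
  expect_lt(abs(baseRate - 0.05), 0.05)
})

test_that("significant counts tally per cell type, setting and matrix", {
  study <- generateStudy(tinyConfig(seed = 87), nDonors = 3L)
  rt <- studyRoiTable(study, topK = 40L)
  dts <- list(differentialTable(rt, "RBC"), differentialTable(rt, "WBC"))
  ct <- countSignificant(dts)
  expect_setequal(ct$cellType, c("RBC", "WBC"))
  expect_equal(ct$nSignificant[ct$cellType == "RBC"],
               sum(dts[[1]]$significant))
  expect_equal(unique(ct$matrixLabel), "9AA")
  expect_equal(unique(ct$settingLabel), "D0")
})
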