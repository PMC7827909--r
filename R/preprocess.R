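#' TIC-normalize a spectrum
#'
#' Divides the intensities by their sum (the total ion count), so the
#' normalized spectrum sums to 1. Idempotent.
#'
#' @param spectrum list with `mz` and `intensity` (as from [getSpectrum()]).
#' @return The spectrum with normalized intensities.
#' @examples
#' ticNormalize(list(mz = 1:3, intensity = c(2, 3, 5)))$intensity
#' @export
ticNormalize <- function(spectrum) {
  tic <- sum(spectrum$intensity)
  if (!is.finite(tic) || tic <= 0)
    stop("cannot TIC-normalize a spectrum with no positive intensity")
  spectrum$intensity <- spectrum$intensity / tic
  spectrum
}

#' Bin a spectrum into fixed-width m/z bins with centroids
#'
#' Bins are half-open intervals `[low + k*w, low + (k+1)*w)` anchored at the
#' lower bound of the acquisition range; a point exactly on a bin edge
#' belongs to the upper bin. Per occupied bin the intensity is the sum of
#' member intensities and the reported m/z is the intensity-weighted mean of
#' member m/z (falling back to the plain mean when the bin's total intensity
#' is zero). Empty bins are omitted. Binning conserves total intensity
#' exactly.
#'
#' @param spectrum list with `mz` and `intensity`.
#' @param binWidth Bin width in Da (default 0.020).
#' @param range Length-2 numeric; the acquisition m/z range whose lower bound
#'   anchors the bin grid.
#' @return data.frame with columns `bin` (0-based bin index), `mz` (centroid)
#'   and `intensity`.
#' @examples
#' binCentroids(list(mz = c(200.003, 200.015), intensity = c(1, 3)),
#'              binWidth = 0.020, range = c(200, 600))
#' @export
binCentroids <- function(spectrum, binWidth = 0.020, range) {
  stopifnot(binWidth > 0, length(range) == 2L)
  bin <- floor((spectrum$mz - range[1]) / binWidth)
  tot <- rowsum(spectrum$intensity, bin)
  wmz <- rowsum(spectrum$mz * spectrum$intensity, bin)
  smz <- rowsum(spectrum$mz, bin)
  cnt <- rowsum(rep(1, length(bin)), bin)
  centroid <- ifelse(tot[, 1] > 0, wmz[, 1] / tot[, 1], smz[, 1] / cnt[, 1])
  data.frame(bin = as.integer(rownames(tot)), mz = centroid,
             intensity = tot[, 1], row.names = NULL)
}

#' Filter peaks by relative intensity
#'
#' Keeps the peaks whose intensity is strictly greater than
#' `fraction * referenceMax` (the published rule: intensity greater than 0.1%
#' of the highest signal in the mass spectrum).
#'
#' @param peaks data.frame with an `intensity` column (e.g. from
#'   [binCentroids()]).
#' @param referenceMax The reference maximum (> 0); in the dataset-level
#'   pipeline this is the maximum of the pixel-averaged TIC-normalized
#'   spectrum.
#' @param fraction Relative threshold (default 0.001).
#' @return The surviving rows of `peaks`.
#' @export
thresholdFilter <- function(peaks, referenceMax, fraction = 0.001) {
  stopifnot(referenceMax > 0, fraction >= 0)
  peaks[peaks$intensity > fraction * referenceMax, , drop = FALSE]
}

#' Keep the K most intense features of a PeakMatrix
#'
#' Ranks bins by their mean TIC-normalized intensity across pixels (or the
#' maximum across pixels, via `rankBy = "max"`) and keeps the top `k`. Ties
#' are broken in favor of the lower m/z. If fewer than `k` bins exist, all
#' are kept. Rows stay in ascending m/z order.
#'
#' @param peakMatrix A [PeakMatrix-class].
#' @param k Number of features to keep (default 500, the published cap).
#' @param rankBy `"mean"` (default) or `"max"`.
#' @return A [PeakMatrix-class] with at most `k` rows.
#' @export
selectTopK <- function(peakMatrix, k = 500L, rankBy = c("mean", "max")) {
  stopifnot(is(peakMatrix, "PeakMatrix"), k >= 1L)
  rankBy <- match.arg(rankBy)
  a <- assay(peakMatrix)
  score <- if (rankBy == "mean") rowMeans(a) else apply(a, 1L, max)
  ord <- order(-score, rowData(peakMatrix)$mz)
  keep <- sort(ord[seq_len(min(k, nrow(a)))])
  out <- peakMatrix[keep, ]
  md <- metadata(out)
  md$topK <- as.integer(k)
  md$rankBy <- rankBy
  metadata(out) <- md
  out
}

#' Build the TIC-normalized binned feature matrix of a dataset
#'
#' The full preprocessing chain: per-pixel TIC normalization, binning of all
#' pixels on one shared 0.020 Da grid anchored at the acquisition range lower
#' bound, relative-intensity thresholding, and top-K selection. Pixels whose
#' spectra are entirely zero are excluded (and recorded in the result's
#' `metadata()$excludedPixels`), not imputed. Each kept bin's m/z is its
#' global intensity-weighted centroid over all included pixels.
#'
#' By default the 0.1%-of-maximum threshold is evaluated against the maximum
#' of the pixel-averaged TIC-normalized spectrum, i.e. bins whose mean
#' intensity is strictly above `thresholdFraction * max(mean spectrum)`
#' survive; `thresholdPerPixel = TRUE` instead zeroes, per pixel, entries
#' below `thresholdFraction` times that pixel's maximum, then drops bins left
#' empty.
#'
#' @param dataset An [MSIDataset-class].
#' @param binWidth Bin width in Da (default 0.020).
#' @param thresholdFraction Relative intensity threshold (default 0.001).
#' @param topK Feature cap (default 500); `Inf` disables.
#' @param thresholdPerPixel Evaluate the threshold per pixel instead of on
#'   the average spectrum.
#' @param rankBy Ranking key for top-K selection, `"mean"` or `"max"`.
#' @return A [PeakMatrix-class].
#' @examples
#' sim <- generateSmear(smearSimConfig(nX = 10L, nY = 10L, seed = 2))
#' pm <- buildFeatureMatrix(sim$dataset)
#' pm
#' @export
buildFeatureMatrix <- function(dataset, binWidth = 0.020,
                               thresholdFraction = 0.001, topK = 500L,
                               thresholdPerPixel = FALSE,
                               rankBy = c("mean", "max")) {
  stopifnot(is(dataset, "MSIDataset"))
  rankBy <- match.arg(rankBy)
  np <- nPixels(dataset)
  lo <- mzRange(dataset)[1]

  if (isContinuous(dataset)) {
    raw <- dataset@intensity
    tics <- colSums(raw)
    included <- which(tics > 0)
    if (!length(included)) stop("every pixel spectrum is empty")
    norm <- raw[, included, drop = FALSE] /
      rep(tics[included], each = nrow(raw))
    bin <- floor((dataset@mz - lo) / binWidth)
    binned <- rowsum(norm, bin)                 # bins x pixels
    wsum <- rowsum(dataset@mz * rowSums(norm), bin)
    tot <- rowSums(binned)
    cnt <- as.vector(rowsum(rep(1, length(bin)), bin))
    centroid <- ifelse(tot > 0, wsum[, 1] / tot,
                       as.vector(rowsum(dataset@mz, bin)) / cnt)
    binIdx <- as.integer(rownames(binned))
  } else {
    included <- which(vapply(dataset@spectraIntensity, sum, numeric(1)) > 0)
    if (!length(included)) stop("every pixel spectrum is empty")
    perPixel <- lapply(included, function(k) {
      binCentroids(ticNormalize(getSpectrum(dataset, k)),
                   binWidth = binWidth, range = mzRange(dataset))
    })
    binIdx <- sort(unique(unlist(lapply(perPixel, `[[`, "bin"))))
    binned <- matrix(0, length(binIdx), length(included))
    wsum <- tsum <- csum <- numeric(length(binIdx))
    for (c_i in seq_along(perPixel)) {
      pp <- perPixel[[c_i]]
      r <- match(pp$bin, binIdx)
      binned[r, c_i] <- pp$intensity
      wsum[r] <- wsum[r] + pp$mz * pp$intensity
      tsum[r] <- tsum[r] + pp$intensity
      csum[r] <- csum[r] + 1
    }
    centroid <- ifelse(tsum > 0, wsum / tsum,
                       (lo + (binIdx + 0.5) * binWidth))
  }

  if (thresholdPerPixel) {
    pixMax <- apply(binned, 2L, max)
    binned[binned <= outer(rep(thresholdFraction, nrow(binned)), pixMax)] <- 0
    keep <- rowSums(binned) > 0
  } else {
    meanSpec <- rowMeans(binned)
    keep <- meanSpec > thresholdFraction * max(meanSpec)
  }
  binned <- binned[keep, , drop = FALSE]
  centroid <- centroid[keep]

  pc <- pixelCoords(dataset)[included, , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(intensity = unname(binned)),
    rowData = S4Vectors::DataFrame(mz = unname(centroid),
                                   bin = binIdx[keep]),
    colData = S4Vectors::DataFrame(pixel = pc$pixel, i = pc$i, j = pc$j))
  metadata(se) <- list(
    binWidth = binWidth, thresholdFraction = thresholdFraction,
    thresholdPerPixel = thresholdPerPixel,
    excludedPixels = setdiff(seq_len(np), included),
    mzRange = mzRange(dataset), polarity = polarity(dataset),
    matrixLabel = dataset@matrixLabel, settingLabel = dataset@settingLabel)
  pm <- new("PeakMatrix", se)
  if (is.finite(topK)) pm <- selectTopK(pm, topK, rankBy = rankBy)
  pm
}

#' Concatenate feature matrices from neighboring m/z ranges
#'
#' The study design records each smear over two neighboring m/z ranges
#' (200-600 and 600-900 Da) that are preprocessed separately; this
#' concatenates their feature matrices over the same pixels. The feature
#' count of the result is the sum of the inputs' feature counts.
#'
#' @param ... [PeakMatrix-class] objects over identical pixel sets.
#' @return A [PeakMatrix-class].
#' @export
combinePeakMatrices <- function(...) {
  pms <- list(...)
  if (length(pms) == 1L && is.list(pms[[1]])) pms <- pms[[1]]
  stopifnot(length(pms) >= 1L, all(vapply(pms, is, logical(1), "PeakMatrix")))
  px <- lapply(pms, function(p) colData(p)$pixel)
  if (!all(vapply(px, identical, logical(1), px[[1]])))
    stop("feature matrices cover different pixel sets")
  ord <- order(vapply(pms, function(p) min(rowData(p)$mz), numeric(1)))
  pms <- pms[ord]
  se <- do.call(rbind, lapply(pms, methods::as, "SummarizedExperiment"))
  metadata(se) <- list(combined = lapply(pms, metadata))
  new("PeakMatrix", se)
}

#' @describeIn buildFeatureMatrix Bin centroid m/z of a PeakMatrix.
#' @param peakMatrix A [PeakMatrix-class].
#' @export
featureMz <- function(peakMatrix) rowData(peakMatrix)$mz
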