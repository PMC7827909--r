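#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' MSIDataset: a pixel grid of mass spectra
#'
#' Container for one MSI acquisition: a rectangular `nX` by `nY` pixel grid at
#' a fixed pitch, with one mass spectrum per pixel, plus acquisition metadata
#' (ionization polarity, MALDI matrix, instrument preset, m/z range).
#'
#' Two storage modes are supported. In continuous mode all pixels share one
#' m/z axis and intensities live in a points-by-pixels matrix; in processed
#' mode each pixel carries its own (m/z, intensity) pair of vectors. Pixels
#' are ordered x-fastest: pixel `k` (1-based) sits at 0-based grid position
#' `i = (k-1) %% nX`, `j = (k-1) %/% nX`, and its physical center is at
#' `((i+0.5)*pitchX, (j+0.5)*pitchY)` in micrometers, with the origin at the
#' grid corner.
#'
#' @slot mz numeric, shared m/z axis (continuous mode; length 0 otherwise).
#' @slot intensity matrix, points x pixels (continuous mode).
#' @slot spectraMz,spectraIntensity lists of per-pixel vectors (processed
#'   mode; length 0 otherwise).
#' @slot continuous logical scalar.
#' @slot nX,nY integer pixel counts.
#' @slot pitchX,pitchY pixel pitch in micrometers.
#' @slot polarity `"positive"` or `"negative"`.
#' @slot matrixLabel MALDI matrix, `"9AA"` or `"CHCA"`.
#' @slot settingLabel instrument preset, `"D0"` or `"D1"`.
#' @slot mzRange numeric length 2, acquisition m/z range (Da).
#'
#' @aliases MSIDataset
#' @exportClass MSIDataset
setClass("MSIDataset", representation(
  mz = "numeric",
  intensity = "matrix",
  spectraMz = "list",
  spectraIntensity = "list",
  continuous = "logical",
  nX = "integer",
  nY = "integer",
  pitchX = "numeric",
  pitchY = "numeric",
  polarity = "character",
  matrixLabel = "character",
  settingLabel = "character",
  mzRange = "numeric"
))

setValidity("MSIDataset", function(object) {
  msg <- character()
  np <- object@nX * object@nY
  if (object@nX < 1L || object@nY < 1L) msg <- c(msg, "nX and nY must be >= 1")
  if (object@pitchX <= 0 || object@pitchY <= 0)
    msg <- c(msg, "pitch values must be > 0")
  if (!object@polarity %in% c("positive", "negative"))
    msg <- c(msg, "polarity must be 'positive' or 'negative'")
  if (length(object@mzRange) != 2L || diff(object@mzRange) <= 0)
    msg <- c(msg, "mzRange must be an increasing length-2 numeric")
  if (isTRUE(object@continuous)) {
    if (ncol(object@intensity) != np)
      msg <- c(msg, "intensity matrix must have one column per pixel")
    if (nrow(object@intensity) != length(object@mz))
      msg <- c(msg, "intensity rows must match m/z axis length")
    if (length(object@mz) && is.unsorted(object@mz, strictly = TRUE))
      msg <- c(msg, "m/z axis must be strictly ascending")
    if (anyNA(object@intensity) || (length(object@intensity) &&
        min(object@intensity) < 0))
      msg <- c(msg, "intensities must be finite and >= 0")
    if (length(object@mz) && (min(object@mz) < object@mzRange[1] ||
        max(object@mz) > object@mzRange[2]))
      msg <- c(msg, "m/z values must lie within mzRange")
  } else {
    if (length(object@spectraMz) != np || length(object@spectraIntensity) != np)
      msg <- c(msg, "every pixel must have a spectrum")
    for (k in seq_len(np)) {
      mzk <- object@spectraMz[[k]]
      ik <- object@spectraIntensity[[k]]
      if (length(mzk) != length(ik)) {
        msg <- c(msg, sprintf("pixel %d: m/z and intensity lengths differ", k))
        break
      }
      if (anyNA(mzk) || anyNA(ik)) {
        msg <- c(msg, sprintf("pixel %d: NaN in spectrum", k)); break
      }
      if (length(mzk) && is.unsorted(mzk, strictly = TRUE)) {
        msg <- c(msg, sprintf("pixel %d: m/z not strictly ascending", k)); break
      }
      if (length(ik) && min(ik) < 0) {
        msg <- c(msg, sprintf("pixel %d: negative intensity", k)); break
      }
      if (length(mzk) && (min(mzk) < object@mzRange[1] ||
          max(mzk) > object@mzRange[2])) {
        msg <- c(msg, sprintf("pixel %d: m/z outside mzRange", k)); break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ROISet: labeled elliptical regions of interest
#'
#' A set of rotated ellipses in the micrometer frame of an [MSIDataset-class],
#' each labeled `RBC`, `WBC` or `plasma` and tagged with donor and smear
#' identifiers. The blood-smear study design uses 5 RBC + 1 WBC + 3 plasma
#' ROIs per smear.
#'
#' @slot rois data.frame with columns `label`, `centerX`, `centerY` (um),
#'   `semiX`, `semiY` (um), `rotation` (degrees), `donor`, `smear`.
#'
#' @aliases ROISet
#' @exportClass ROISet
setClass("ROISet", representation(rois = "data.frame"))

.ROI_COLUMNS <- c("label", "centerX", "centerY", "semiX", "semiY",
                  "rotation", "donor", "smear")

setValidity("ROISet", function(object) {
  df <- object@rois
  msg <- character()
  missing <- setdiff(.ROI_COLUMNS, names(df))
  if (length(missing))
    return(paste("missing ROI column(s):", paste(missing, collapse = ", ")))
  if (nrow(df)) {
    if (!all(df$label %in% c("RBC", "WBC", "plasma")))
      msg <- c(msg, "labels must be RBC, WBC or plasma")
    if (any(df$semiX <= 0) || any(df$semiY <= 0))
      msg <- c(msg, "semi-axes must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' PeakMatrix: binned TIC-normalized feature matrix
#'
#' A [SummarizedExperiment-class] subclass holding the preprocessed feature
#' matrix of one MSI dataset: rows are m/z bins (with `rowData` column `mz`,
#' the intensity-weighted bin centroid in Da) and columns are pixels (with
#' `colData` columns `i`, `j`, `pixel`). The single assay `intensity` holds
#' TIC-normalized binned intensities, so every pixel's column sum is at most
#' 1. Preprocessing provenance (bin width, threshold fraction, top-K, source
#' dataset id, excluded pixels) is carried in `metadata()`.
#'
#' @aliases PeakMatrix
#' @exportClass PeakMatrix
setClass("PeakMatrix", contains = "SummarizedExperiment")

setValidity("PeakMatrix", function(object) {
  msg <- character()
  if (!"mz" %in% names(rowData(object)))
    return("rowData must contain an 'mz' column")
  mz <- rowData(object)$mz
  if (length(mz) > 1L && is.unsorted(mz, strictly = TRUE))
    msg <- c(msg, "bin centroids must be strictly ascending")
  a <- assay(object)
  if (anyNA(a) || (length(a) && min(a) < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  # one TIC-normalized range sums to <= 1 per pixel; a concatenation of
  # ranges to <= (number of ranges)
  nRanges <- max(1L, length(metadata(object)$combined))
  if (length(a) && any(colSums(a) > nRanges + 1e-9))
    msg <- c(msg, "per-pixel intensity sums must not exceed 1 (TIC scale)")
  if (length(msg)) msg else TRUE
})
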