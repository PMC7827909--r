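#' Construct an MSIDataset
#'
#' @param mz Either a single strictly ascending numeric vector (continuous
#'   mode: all pixels share the axis) or a list of per-pixel vectors
#'   (processed mode).
#' @param intensity A points-by-pixels matrix (continuous) or a list of
#'   per-pixel intensity vectors (processed).
#' @param nX,nY Pixel counts along x and y.
#' @param pitchX,pitchY Pixel pitch in micrometers. The instrument presets are
#'   8 x 7 um (D0) and 8 x 6 um (D1).
#' @param polarity `"positive"` or `"negative"`.
#' @param matrixLabel MALDI matrix label, `"9AA"` or `"CHCA"`.
#' @param settingLabel Instrument preset label, `"D0"` or `"D1"`.
#' @param mzRange Acquisition m/z range `c(low, high)` in Da; defaults to the
#'   span of the data, slightly padded.
#' @return An [MSIDataset-class].
#' @examples
#' d <- MSIDataset(mz = c(300, 300.01, 300.02),
#'                 intensity = matrix(1, 3, 4), nX = 2, nY = 2)
#' d
#' @export
MSIDataset <- function(mz, intensity, nX, nY,
                       pitchX = 8, pitchY = 7,
                       polarity = "negative", matrixLabel = "9AA",
                       settingLabel = "D0", mzRange = NULL) {
  continuous <- !is.list(mz)
  if (is.null(mzRange)) {
    allmz <- if (continuous) mz else unlist(mz, use.names = FALSE)
    if (!length(allmz)) stop("cannot infer mzRange from empty spectra")
    mzRange <- c(floor(min(allmz)), ceiling(max(allmz)))
    if (diff(mzRange) <= 0) mzRange <- mzRange + c(-1, 1)
  }
  if (continuous) {
    intensity <- as.matrix(intensity)
    new("MSIDataset", mz = as.numeric(mz), intensity = intensity,
        spectraMz = list(), spectraIntensity = list(), continuous = TRUE,
        nX = as.integer(nX), nY = as.integer(nY),
        pitchX = as.numeric(pitchX), pitchY = as.numeric(pitchY),
        polarity = polarity, matrixLabel = matrixLabel,
        settingLabel = settingLabel, mzRange = as.numeric(mzRange))
  } else {
    new("MSIDataset", mz = numeric(), intensity = matrix(numeric(), 0, 0),
        spectraMz = lapply(mz, as.numeric),
        spectraIntensity = lapply(intensity, as.numeric), continuous = FALSE,
        nX = as.integer(nX), nY = as.integer(nY),
        pitchX = as.numeric(pitchX), pitchY = as.numeric(pitchY),
        polarity = polarity, matrixLabel = matrixLabel,
        settingLabel = settingLabel, mzRange = as.numeric(mzRange))
  }
}

#' @describeIn MSIDataset Number of pixels.
#' @param object,x An `MSIDataset`.
#' @export
nPixels <- function(object) object@nX * object@nY

#' @describeIn MSIDataset Grid dimensions `c(nX, nY)`.
#' @export
gridDim <- function(object) c(nX = object@nX, nY = object@nY)

#' @describeIn MSIDataset Pixel pitch `c(pitchX, pitchY)` in micrometers.
#' @export
pitch <- function(object) c(pitchX = object@pitchX, pitchY = object@pitchY)

#' @describeIn MSIDataset Ionization polarity.
#' @export
polarity <- function(object) object@polarity

#' @describeIn MSIDataset Acquisition m/z range.
#' @export
mzRange <- function(object) object@mzRange

#' @describeIn MSIDataset `TRUE` if all pixels share one m/z axis.
#' @export
isContinuous <- function(object) isTRUE(object@continuous)

#' Pixel coordinates of an MSIDataset
#'
#' Returns the 0-based grid indices and physical centers (micrometers) of all
#' pixels, in pixel order (x-fastest).
#'
#' @param object An [MSIDataset-class].
#' @return data.frame with columns `pixel` (1-based index), `i`, `j`
#'   (0-based grid position) and `x`, `y` (center, um).
#' @export
pixelCoords <- function(object) {
  k <- seq_len(nPixels(object)) - 1L
  i <- k %% object@nX
  j <- k %/% object@nX
  data.frame(pixel = k + 1L, i = i, j = j,
             x = (i + 0.5) * object@pitchX,
             y = (j + 0.5) * object@pitchY)
}

#' Extract one pixel's spectrum
#'
#' @param object An [MSIDataset-class].
#' @param pixel 1-based pixel index.
#' @return list with elements `mz` and `intensity`.
#' @export
getSpectrum <- function(object, pixel) {
  stopifnot(length(pixel) == 1L, pixel >= 1L, pixel <= nPixels(object))
  if (isContinuous(object))
    list(mz = object@mz, intensity = object@intensity[, pixel])
  else
    list(mz = object@spectraMz[[pixel]],
         intensity = object@spectraIntensity[[pixel]])
}

#' Total ion count per pixel
#'
#' @param object An [MSIDataset-class].
#' @return numeric vector, one TIC per pixel.
#' @export
pixelTIC <- function(object) {
  if (isContinuous(object)) colSums(object@intensity)
  else vapply(object@spectraIntensity, sum, numeric(1))
}

setMethod("show", "MSIDataset", function(object) {
  cat(sprintf("MSIDataset: %d x %d pixels @ %g x %g um (%s)\n",
              object@nX, object@nY, object@pitchX, object@pitchY,
              if (isContinuous(object)) "continuous" else "processed"))
  cat(sprintf("  polarity: %s | matrix: %s | setting: %s | m/z %g-%g Da\n",
              object@polarity, object@matrixLabel, object@settingLabel,
              object@mzRange[1], object@mzRange[2]))
  npts <- if (isContinuous(object)) length(object@mz)
          else round(mean(lengths(object@spectraMz)))
  cat(sprintf("  %s%d m/z points per pixel\n",
              if (isContinuous(object)) "" else "~", npts))
})

#' Construct a ROISet
#'
#' @param label Character vector of ROI labels (`RBC`, `WBC` or `plasma`).
#' @param centerX,centerY Ellipse centers in micrometers.
#' @param semiX,semiY Ellipse semi-axes in micrometers (> 0).
#' @param rotation Ellipse rotation in degrees (counterclockwise), default 0.
#' @param donor,smear Identifier columns, recycled.
#' @return A [ROISet-class].
#' @examples
#' ROISet(label = c("RBC", "plasma"), centerX = c(20, 60),
#'        centerY = c(17.5, 40), semiX = c(4, 8), semiY = c(3.5, 7))
#' @export
ROISet <- function(label, centerX, centerY, semiX, semiY,
                   rotation = 0, donor = 1L, smear = 1L) {
  n <- length(label)
  df <- data.frame(label = as.character(label),
                   centerX = as.numeric(centerX),
                   centerY = as.numeric(centerY),
                   semiX = as.numeric(semiX),
                   semiY = as.numeric(semiY),
                   rotation = rep_len(as.numeric(rotation), n),
                   donor = rep_len(donor, n),
                   smear = rep_len(smear, n),
                   stringsAsFactors = FALSE)
  new("ROISet", rois = df)
}

#' @describeIn ROISet Underlying ROI table.
#' @param object A `ROISet`.
#' @export
rois <- function(object) object@rois

#' @describeIn ROISet Number of ROIs.
#' @export
nROI <- function(object) nrow(object@rois)

setMethod("show", "ROISet", function(object) {
  tab <- table(object@rois$label)
  cat(sprintf("ROISet: %d ROIs (%s), %d donor(s)\n", nROI(object),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(unique(object@rois$donor))))
})

setMethod("length", "ROISet", function(x) nROI(x))

#' Pixels covered by an elliptical ROI
#'
#' A pixel belongs to the ROI if and only if its physical center
#' `((i+0.5)*pitchX, (j+0.5)*pitchY)` satisfies the rotated-ellipse
#' containment inequality (value <= 1). Membership is by center containment,
#' not area overlap.
#'
#' @param dataset An [MSIDataset-class].
#' @param roi A single-row data.frame (one row of [rois()]) or a list with
#'   fields `centerX`, `centerY`, `semiX`, `semiY`, `rotation`.
#' @return Integer vector of 1-based pixel indices (possibly empty; an ROI
#'   entirely outside the grid yields an empty vector with a warning).
#' @examples
#' d <- MSIDataset(mz = 300, intensity = matrix(1, 1, 25), nX = 5, nY = 5)
#' pixelsInRoi(d, list(centerX = 20, centerY = 17.5, semiX = 4, semiY = 4,
#'                     rotation = 0))
#' @export
pixelsInRoi <- function(dataset, roi) {
  if (is.data.frame(roi)) {
    stopifnot(nrow(roi) == 1L)
    roi <- as.list(roi)
  }
  rot <- if (is.null(roi$rotation)) 0 else roi$rotation
  stopifnot(roi$semiX > 0, roi$semiY > 0)
  pc <- pixelCoords(dataset)
  dx <- pc$x - roi$centerX
  dy <- pc$y - roi$centerY
  th <- rot * pi / 180
  u <- (dx * cos(th) + dy * sin(th)) / roi$semiX
  v <- (-dx * sin(th) + dy * cos(th)) / roi$semiY
  idx <- pc$pixel[u * u + v * v <= 1]
  if (!length(idx))
    warning("ROI covers no pixel centers", call. = FALSE)
  idx
}
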