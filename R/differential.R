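#' ROISampleTable: per-ROI mean feature intensities
#'
#' Aggregation of a [PeakMatrix-class] over the pixels of each ROI: one row
#' per ROI (the sampling unit of the differential analysis), one column per
#' m/z feature; values are arithmetic means of the TIC-normalized binned
#' intensities over the ROI's member pixels.
#'
#' @slot values numeric matrix, ROIs by features.
#' @slot roiInfo data.frame with `label`, `donor`, `smear`, `nPixels` per ROI.
#' @slot mz numeric, feature centroid m/z.
#' @slot labels list of dataset labels (matrix, setting, polarity).
#'
#' @aliases ROISampleTable
#' @exportClass ROISampleTable
setClass("ROISampleTable", representation(
  values = "matrix", roiInfo = "data.frame", mz = "numeric",
  labels = "list"))

setValidity("ROISampleTable", function(object) {
  msg <- character()
  if (nrow(object@values) != nrow(object@roiInfo))
    msg <- c(msg, "one roiInfo row per value row required")
  if (ncol(object@values) != length(object@mz))
    msg <- c(msg, "one mz per value column required")
  if (nrow(object@roiInfo) &&
      !all(object@roiInfo$label %in% c("RBC", "WBC", "plasma")))
    msg <- c(msg, "ROI labels must be RBC, WBC or plasma")
  if (nrow(object@roiInfo) && any(object@roiInfo$nPixels < 1L))
    msg <- c(msg, "every ROI must have at least one member pixel")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ROISampleTable", function(object) {
  tab <- table(object@roiInfo$label)
  cat(sprintf("ROISampleTable: %d ROIs (%s) x %d features\n",
              nrow(object@values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(object@mz)))
})

#' @describeIn aggregateRois ROI-by-feature value matrix.
#' @export
roiValues <- function(object) object@values

#' @describeIn aggregateRois Per-ROI metadata (`label`, `donor`, `smear`,
#'   `nPixels`).
#' @export
roiInfo <- function(object) object@roiInfo

#' Aggregate a feature matrix over ROIs
#'
#' Computes, for every ROI, the arithmetic mean of each feature over the
#' ROI's member pixels (pixel membership by ellipse center containment, see
#' [pixelsInRoi()]). ROIs that cover no pixel of the feature matrix are
#' dropped with a warning; it is an error if none remains. Features absent
#' from a pixel are zeros in the feature matrix already, so no further
#' filling is needed.
#'
#' @param peakMatrix A [PeakMatrix-class].
#' @param roiSet A [ROISet-class] in the dataset's micrometer frame.
#' @param dataset The source [MSIDataset-class] (supplies grid geometry).
#' @param object A `ROISampleTable`.
#' @return A [ROISampleTable-class].
#' @export
aggregateRois <- function(peakMatrix, roiSet, dataset) {
  stopifnot(is(peakMatrix, "PeakMatrix"), is(roiSet, "ROISet"),
            is(dataset, "MSIDataset"))
  df <- rois(roiSet)
  colPixel <- colData(peakMatrix)$pixel
  a <- assay(peakMatrix)
  rows <- vector("list", nrow(df))
  keep <- logical(nrow(df))
  npix <- integer(nrow(df))
  for (r in seq_len(nrow(df))) {
    idx <- suppressWarnings(pixelsInRoi(dataset, df[r, ]))
    cols <- match(idx, colPixel)
    cols <- cols[!is.na(cols)]
    if (!length(cols)) {
      warning(sprintf("ROI %d (%s) covers no pixels; dropped", r,
                      df$label[r]), call. = FALSE)
      next
    }
    keep[r] <- TRUE
    npix[r] <- length(cols)
    rows[[r]] <- rowMeans(a[, cols, drop = FALSE])
  }
  if (!any(keep)) stop("all ROIs are empty")
  md <- metadata(peakMatrix)
  new("ROISampleTable",
      values = do.call(rbind, rows[keep]),
      roiInfo = data.frame(label = df$label[keep], donor = df$donor[keep],
                           smear = df$smear[keep], nPixels = npix[keep],
                           stringsAsFactors = FALSE),
      mz = featureMz(peakMatrix),
      labels = md[intersect(c("matrixLabel", "settingLabel", "polarity"),
                            names(md))])
}

#' Two-sample t-test for one feature
#'
#' Welch's unequal-variance two-sample t-test (the default; pooled-variance
#' via `varEqual = TRUE`), two-sided. Degenerate inputs follow fixed
#' conventions: if both groups have zero variance and equal means, `t = 0`
#' and `p = 1`; if both have zero variance and different means, `t` is signed
#' infinite and `p = 0`.
#'
#' @param cellValues,plasmaValues Numeric vectors, at least 2 values each.
#' @param varEqual Use the pooled-variance statistic instead of Welch.
#' @return Named list with `t` and `p`.
#' @examples
#' tTestFeature(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
tTestFeature <- function(cellValues, plasmaValues, varEqual = FALSE) {
  if (length(cellValues) < 2L || length(plasmaValues) < 2L)
    stop("each group needs at least 2 values")
  v1 <- stats::var(cellValues); v2 <- stats::var(plasmaValues)
  if (v1 == 0 && v2 == 0) {
    d <- mean(cellValues) - mean(plasmaValues)
    if (d == 0) return(list(t = 0, p = 1))
    return(list(t = sign(d) * Inf, p = 0))
  }
  ht <- stats::t.test(cellValues, plasmaValues, var.equal = varEqual)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Differential m/z expression between a cell type and plasma
#'
#' Tests every feature of a [ROISampleTable-class] between the ROIs of one
#' cell type and the plasma-remnant ROIs, with a two-sided two-sample t-test
#' at significance limit `alpha`, and reports the fold change (mean cell /
#' mean plasma; a zero plasma mean gives an infinite fold change, flagged).
#' No multiple-testing correction is applied by default (the raw
#' significance limit is the published procedure); Benjamini-Hochberg is
#' available via `adjust = "BH"`.
#'
#' @param roiTable A [ROISampleTable-class].
#' @param cellType `"RBC"` or `"WBC"`.
#' @param alpha Significance limit (default 0.05).
#' @param varEqual Pooled-variance t-test instead of Welch.
#' @param adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return A data.frame (one row per feature): `mz`, `t`, `p`, `foldChange`,
#'   `infiniteFold`, `significant`, `cellType`, plus the dataset labels
#'   carried by the table.
#' @examples
#' sim <- generateSmear(smearSimConfig(nX = 14L, nY = 14L, seed = 4))
#' pm <- buildFeatureMatrix(sim$dataset)
#' rt <- aggregateRois(pm, sim$roiSet, sim$dataset)
#' dt <- differentialTable(rt, "RBC")
#' head(dt[order(dt$p), ])
#' @export
differentialTable <- function(roiTable, cellType = c("RBC", "WBC"),
                              alpha = 0.05, varEqual = FALSE,
                              adjust = "none") {
  stopifnot(is(roiTable, "ROISampleTable"), alpha >= 0, alpha <= 1)
  cellType <- match.arg(cellType)
  lab <- roiInfo(roiTable)$label
  cellRows <- which(lab == cellType)
  plasmaRows <- which(lab == "plasma")
  if (!length(plasmaRows)) stop("no plasma ROIs in the table")
  if (length(cellRows) < 2L || length(plasmaRows) < 2L)
    stop("need at least 2 ROIs per group for the t-test")
  v <- roiValues(roiTable)
  res <- vapply(seq_along(roiTable@mz), function(f) {
    ht <- tTestFeature(v[cellRows, f], v[plasmaRows, f], varEqual = varEqual)
    mc <- mean(v[cellRows, f]); mp <- mean(v[plasmaRows, f])
    fc <- if (mp > 0) mc / mp else Inf
    c(ht$t, ht$p, fc)
  }, numeric(3))
  p <- stats::p.adjust(res[2, ], method = adjust)
  out <- data.frame(
    mz = roiTable@mz, t = res[1, ], p = p,
    foldChange = res[3, ], infiniteFold = !is.finite(res[3, ]),
    significant = p < alpha, cellType = cellType,
    stringsAsFactors = FALSE)
  for (nm in names(roiTable@labels)) out[[nm]] <- roiTable@labels[[nm]]
  attr(out, "alpha") <- alpha
  out
}

#' Differential signal counts in the published layout
#'
#' Tallies significant features per (cell type, instrument setting, MALDI
#' matrix) across one or more differential tables; tables from neighboring
#' m/z ranges of the same condition are combined by summing their counts
#' (their features are disjoint by construction).
#'
#' @param ... Differential tables from [differentialTable()], or one list of
#'   them.
#' @return data.frame with columns `cellType`, `settingLabel`,
#'   `matrixLabel`, `nSignificant`.
#' @export
countSignificant <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.data.frame(tabs[[1]]) == FALSE)
    tabs <- tabs[[1]]
  stopifnot(length(tabs) >= 1L)
  all <- do.call(rbind, lapply(tabs, function(d) {
    if (!"settingLabel" %in% names(d)) d$settingLabel <- NA_character_
    if (!"matrixLabel" %in% names(d)) d$matrixLabel <- NA_character_
    d[, c("cellType", "settingLabel", "matrixLabel", "significant")]
  }))
  agg <- stats::aggregate(significant ~ cellType + settingLabel + matrixLabel,
                          data = all, FUN = sum)
  names(agg)[names(agg) == "significant"] <- "nSignificant"
  agg
}
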