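#' Simulation configuration for a synthetic blood-smear MSI dataset
#'
#' Builds the configuration of the synthetic smear generator. The generator
#' emulates the structure the downstream analysis assumes: a rectangular
#' pixel grid at the D0 (8 x 7 um) or D1 (8 x 6 um) pitch, red and white
#' blood cells dropped as non-overlapping disks on a plasma-remnant
#' background, cellular marker peaks at the published marker m/z with
#' cell-type-dependent enrichment, a dense panel of plasma background peaks,
#' per-pixel multiplicative TIC variation, and additive half-normal baseline
#' noise. Each pixel's profile spectrum is a sum of Gaussian peaks sampled on
#' a fixed grid of points around each peak center, so all pixels share one
#' m/z axis (continuous mode).
#'
#' @param preset Instrument preset, `"D0"` (pitch 8 x 7 um) or `"D1"`
#'   (8 x 6 um).
#' @param mode Matrix/ionization preset: `"9AA-negative"` or
#'   `"CHCA-positive"`.
#' @param nX,nY Grid size in pixels.
#' @param mzRange Acquisition m/z range (Da), `c(200, 600)` or `c(600, 900)`
#'   in the study design.
#' @param nRBC,nWBC Numbers of red/white blood cells dropped on the grid.
#' @param rbcDiameter,wbcDiameter Cell diameters in micrometers (defaults 7
#'   and 12).
#' @param markers data.frame with columns `mz`, `rbc`, `wbc` (enrichment
#'   factors >= 0 relative to plasma; 1 = no enrichment). `NULL` selects the
#'   cellular-marker panel matching `mode`, restricted to `mzRange`.
#' @param nBackgroundPeaks Number of plasma background peaks.
#' @param backgroundAmpSdlog Log-normal sdlog of background peak amplitudes.
#' @param markerAmplitude Base (plasma-level) amplitude of marker peaks, in
#'   units of the median background amplitude.
#' @param plasmaUnderCell Fraction of the plasma background retained under
#'   cell pixels (plasma remnants also cover cells); forced to 1 in null
#'   mode.
#' @param peakSigma Gaussian peak sigma in Da.
#' @param ticSdlog Log-normal sdlog of the per-pixel TIC factor.
#' @param baselineSigma Sigma of the additive half-normal baseline noise, in
#'   units of the median background amplitude.
#' @param donorSdlog Log-normal sdlog of the per-(donor, peak) amplitude
#'   multiplier applied by [generateStudy()].
#' @param nullMode If `TRUE`, all enrichment factors are forced to 1 and the
#'   cell/plasma spectral model is identical for every pixel class, making
#'   ROI samples fully exchangeable (used to audit type-I error control).
#' @param seed RNG seed.
#' @return A list of class `SmearSimConfig`.
#' @examples
#' cfg <- smearSimConfig(seed = 7)
#' str(cfg[c("preset", "mode", "nX", "nY")])
#' @export
smearSimConfig <- function(preset = c("D0", "D1"),
                           mode = c("9AA-negative", "CHCA-positive"),
                           nX = 20L, nY = 20L,
                           mzRange = c(200, 600),
                           nRBC = 18L, nWBC = 2L,
                           rbcDiameter = 7, wbcDiameter = 12,
                           markers = NULL,
                           nBackgroundPeaks = 260L,
                           backgroundAmpSdlog = 1,
                           markerAmplitude = 3,
                           plasmaUnderCell = 0.3,
                           peakSigma = 0.01,
                           ticSdlog = 0.2,
                           baselineSigma = 0.05,
                           donorSdlog = 0.15,
                           nullMode = FALSE,
                           seed = 1L) {
  preset <- match.arg(preset)
  mode <- match.arg(mode)
  polarity <- if (mode == "9AA-negative") "negative" else "positive"
  if (is.null(markers)) markers <- defaultMarkerPanel(polarity, mzRange)
  stopifnot(is.data.frame(markers),
            all(c("mz", "rbc", "wbc") %in% names(markers)),
            all(markers$rbc >= 0), all(markers$wbc >= 0),
            length(mzRange) == 2L, diff(mzRange) > 0,
            nBackgroundPeaks >= 1L, peakSigma > 0, plasmaUnderCell >= 0)
  if (nullMode) {
    markers$rbc <- 1
    markers$wbc <- 1
    plasmaUnderCell <- 1
  }
  structure(list(
    preset = preset, mode = mode, polarity = polarity,
    matrixLabel = if (polarity == "negative") "9AA" else "CHCA",
    pitchX = 8, pitchY = if (preset == "D0") 7 else 6,
    nX = as.integer(nX), nY = as.integer(nY), mzRange = as.numeric(mzRange),
    nRBC = as.integer(nRBC), nWBC = as.integer(nWBC),
    rbcDiameter = rbcDiameter, wbcDiameter = wbcDiameter,
    markers = markers, nBackgroundPeaks = as.integer(nBackgroundPeaks),
    backgroundAmpSdlog = backgroundAmpSdlog,
    markerAmplitude = markerAmplitude,
    plasmaUnderCell = plasmaUnderCell, peakSigma = peakSigma,
    ticSdlog = ticSdlog, baselineSigma = baselineSigma,
    donorSdlog = donorSdlog, nullMode = isTRUE(nullMode),
    seed = as.integer(seed)), class = "SmearSimConfig")
}

#' Default cellular-marker panel for simulation
#'
#' The marker compounds used as MSI quality indicators, at their theoretical
#' adduct m/z, with the simulator's default cell-type enrichment factors:
#' heme strongly enriched in RBC, ATP enriched in both cell types (most in
#' WBC), IMP mildly enriched in RBC.
#'
#' @param polarity `"negative"` or `"positive"`.
#' @param mzRange Optional m/z range used to subset the panel.
#' @return data.frame with columns `name`, `mz`, `rbc`, `wbc`.
#' @export
defaultMarkerPanel <- function(polarity = c("negative", "positive"),
                               mzRange = NULL) {
  polarity <- match.arg(polarity)
  panel <- if (polarity == "negative") {
    data.frame(
      name = c("ATP [M-H]-", "heme(FeII) [M-H]-"),
      mz = c(adductMz(monoisotopicMass("C10H16N5O13P3"), "M-H"),
             adductMz(monoisotopicMass("C34H32FeN4O4"), "M-H")),
      rbc = c(3, 5), wbc = c(5, 1))
  } else {
    data.frame(
      name = c("IMP [M+Na]+", "heme(FeIII) [M]+"),
      mz = c(adductMz(monoisotopicMass("C10H13N4O8P"), "M+Na"),
             adductMz(monoisotopicMass("C34H32FeN4O4"), "M")),
      rbc = c(2, 5), wbc = c(1, 1))
  }
  if (!is.null(mzRange))
    panel <- panel[panel$mz > mzRange[1] & panel$mz < mzRange[2], ,
                   drop = FALSE]
  rownames(panel) <- NULL
  panel
}

# offsets (Da) at which each Gaussian peak is sampled on the shared axis
.peakOffsets <- function(sigma) seq(-3 * sigma, 3 * sigma, by = sigma / 2)

# Peak panel: centers, base amplitudes, per-class factors. Built once per
# study so features align across donors.
.buildPeakPanel <- function(config) {
  lo <- config$mzRange[1] + 0.5
  hi <- config$mzRange[2] - 0.5
  n <- config$nBackgroundPeaks
  centers <- numeric(0)
  for (try in seq_len(100L)) {
    cand <- sort(c(centers, stats::runif(2L * n, lo, hi)))
    keep <- c(TRUE, diff(cand) >= 0.2)  # greedy left-to-right spacing
    while (!all(keep)) {
      cand <- cand[keep]
      keep <- c(TRUE, diff(cand) >= 0.2)
    }
    centers <- cand
    if (length(centers) >= n) break
  }
  if (length(centers) < n)
    stop("cannot place ", n, " background peaks 0.2 Da apart in the range")
  centers <- sort(sample(centers, n))
  bgAmp <- stats::rlnorm(n, meanlog = 0, sdlog = config$backgroundAmpSdlog)
  mk <- config$markers
  # drop background peaks that would collide with a marker window
  keepBg <- if (nrow(mk))
    !vapply(centers, function(x) any(abs(mk$mz - x) < 0.2), logical(1))
  else rep(TRUE, n)
  panel <- data.frame(
    mz = c(centers, mk$mz),
    amplitude = c(bgAmp, rep(config$markerAmplitude, nrow(mk))),
    rbcFactor = c(rep(config$plasmaUnderCell, n), mk$rbc),
    wbcFactor = c(rep(config$plasmaUnderCell, n), mk$wbc),
    plasmaFactor = rep(1, n + nrow(mk)),
    isMarker = c(rep(FALSE, n), rep(TRUE, nrow(mk))))
  panel <- panel[c(keepBg, rep(TRUE, nrow(mk))), ]
  panel <- panel[order(panel$mz), ]
  rownames(panel) <- NULL
  panel
}

# Non-overlapping disk placement by rejection sampling.
.placeCells <- function(config) {
  W <- config$nX * config$pitchX
  H <- config$nY * config$pitchY
  radii <- c(rep(config$wbcDiameter / 2, config$nWBC),
             rep(config$rbcDiameter / 2, config$nRBC))
  type <- c(rep("WBC", config$nWBC), rep("RBC", config$nRBC))
  cx <- cy <- numeric(length(radii))
  for (c_i in seq_along(radii)) {
    r <- radii[c_i]
    if (2 * r > min(W, H)) stop("cell larger than the grid")
    placed <- FALSE
    for (try in seq_len(500L)) {
      x <- runif(1, r, W - r)
      y <- runif(1, r, H - r)
      prev <- seq_len(c_i - 1L)
      if (!length(prev) ||
          all((x - cx[prev])^2 + (y - cy[prev])^2 >
              (r + radii[prev])^2)) {
        cx[c_i] <- x; cy[c_i] <- y; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("cell area demand exceeds grid capacity (placement failed after ",
           "bounded retries)")
  }
  data.frame(type = type, x = cx, y = cy, r = radii)
}

# class label per pixel: WBC > RBC > plasma by disk membership of the center
.labelPixels <- function(config, cells) {
  k <- seq_len(config$nX * config$nY) - 1L
  px <- (k %% config$nX + 0.5) * config$pitchX
  py <- (k %/% config$nX + 0.5) * config$pitchY
  lab <- rep("plasma", length(k))
  owner <- rep(NA_integer_, length(k))
  for (c_i in order(cells$type == "WBC")) {  # RBC first, WBC overrides
    inside <- (px - cells$x[c_i])^2 + (py - cells$y[c_i])^2 <=
      cells$r[c_i]^2
    lab[inside] <- cells$type[c_i]
    owner[inside] <- c_i
  }
  list(label = lab, owner = owner, px = px, py = py)
}

# study-design ROI set: 5 RBC + 1 WBC + 3 plasma ellipses per smear
.designRois <- function(config, cells, pix, donor = 1L, smear = 1L) {
  pickCellRois <- function(type, count, semiX, semiY) {
    cand <- which(cells$type == type)
    centers <- lapply(cand, function(c_i) {
      own <- which(pix$owner == c_i)
      if (!length(own)) return(NULL)
      d2 <- (pix$px[own] - cells$x[c_i])^2 + (pix$py[own] - cells$y[c_i])^2
      own[which.min(d2)]
    })
    ok <- cand[!vapply(centers, is.null, logical(1))]
    centers <- unlist(centers)
    if (length(ok) < count)
      stop("placement yielded too few ", type,
           " cells covering a pixel center; enlarge the grid or cell count")
    sel <- sample(seq_along(ok), count)
    data.frame(label = type, centerX = pix$px[centers[sel]],
               centerY = pix$py[centers[sel]],
               semiX = semiX, semiY = semiY)
  }
  rbc <- pickCellRois("RBC", 5L, 4, 3.5)
  wbc <- pickCellRois("WBC", 1L, 6, 5.5)
  # plasma ROIs: centers whose 4-neighborhood is plasma too
  nXY <- c(config$nX, config$nY)
  k <- seq_along(pix$label) - 1L
  i <- k %% nXY[1]; j <- k %/% nXY[1]
  isPlasma <- matrix(pix$label == "plasma", nXY[1], nXY[2])
  inner <- which(i >= 1 & i <= nXY[1] - 2 & j >= 1 & j <= nXY[2] - 2 &
                 pix$label == "plasma")
  clear <- inner[vapply(inner, function(p) {
    ii <- (p - 1L) %% nXY[1] + 1L; jj <- (p - 1L) %/% nXY[1] + 1L
    isPlasma[ii + 1L, jj] && isPlasma[ii - 1L, jj] &&
      isPlasma[ii, jj + 1L] && isPlasma[ii, jj - 1L]
  }, logical(1))]
  if (length(clear) < 3L) stop("too few clear plasma regions for ROIs")
  sel <- sample(clear, 3L)
  plasma <- data.frame(label = "plasma", centerX = pix$px[sel],
                       centerY = pix$py[sel],
                       semiX = config$pitchX, semiY = config$pitchY)
  df <- rbind(rbc, wbc, plasma)
  ROISet(label = df$label, centerX = df$centerX, centerY = df$centerY,
         semiX = df$semiX, semiY = df$semiY, rotation = 0,
         donor = donor, smear = smear)
}

#' Generate one synthetic blood-smear MSI dataset
#'
#' Simulates a single smear: cells are placed as non-overlapping disks, each
#' pixel receives a profile spectrum equal to the sum of Gaussian peaks with
#' class-dependent amplitudes, scaled by a log-normal per-pixel TIC factor,
#' plus half-normal additive baseline noise. Alongside the dataset it returns
#' the study-design ROI set (5 RBC + 1 WBC + 3 plasma ellipses) and the
#' ground truth (per-pixel class labels and the truly enriched (m/z, cell
#' type) pairs).
#'
#' @param config A [smearSimConfig()].
#' @param panel Optional precomputed peak panel (used by [generateStudy()] so
#'   that features align across donors); by default built from `config`.
#' @param donorMult Optional per-peak amplitude multiplier (donor random
#'   effect), default 1.
#' @param donor,smear Identifiers stamped on the ROI set.
#' @param seed RNG seed for this smear; defaults to `config$seed`.
#' @return A list with elements `dataset` ([MSIDataset-class]), `roiSet`
#'   ([ROISet-class]) and `truth` (list: `pixelClass`, `cells`, `enriched`,
#'   `panel`).
#' @examples
#' sim <- generateSmear(smearSimConfig(nX = 12L, nY = 12L, seed = 3))
#' sim$dataset
#' table(sim$truth$pixelClass)
#' @export
generateSmear <- function(config, panel = NULL, donorMult = NULL,
                          donor = 1L, smear = 1L, seed = config$seed) {
  stopifnot(inherits(config, "SmearSimConfig"))
  set.seed(seed)
  if (is.null(panel)) panel <- .buildPeakPanel(config)
  if (is.null(donorMult)) donorMult <- rep(1, nrow(panel))
  stopifnot(length(donorMult) == nrow(panel))

  # a placement can leave too few cells owning a pixel center; redraw then
  roiSet <- NULL
  for (try in seq_len(25L)) {
    cells <- .placeCells(config)
    pix <- .labelPixels(config, cells)
    roiSet <- tryCatch(
      .designRois(config, cells, pix, donor = donor, smear = smear),
      error = function(e) NULL)
    if (!is.null(roiSet)) break
  }
  if (is.null(roiSet))
    stop("could not realize the ROI design on this grid; ",
         "enlarge the grid or cell counts")

  offsets <- .peakOffsets(config$peakSigma)
  shape <- exp(-offsets^2 / (2 * config$peakSigma^2))
  npk <- nrow(panel)
  axis <- rep(panel$mz, each = length(offsets)) + offsets
  stopifnot(!is.unsorted(axis, strictly = TRUE))

  amp <- panel$amplitude * donorMult
  classAmp <- cbind(RBC = amp * panel$rbcFactor,
                    WBC = amp * panel$wbcFactor,
                    plasma = amp * panel$plasmaFactor)
  base <- classAmp[rep(seq_len(npk), each = length(offsets)), ] *
    rep(shape, npk)  # points x 3 classes
  classIdx <- match(pix$label, colnames(classAmp))

  np <- config$nX * config$nY
  tic <- stats::rlnorm(np, meanlog = 0, sdlog = config$ticSdlog)
  intensity <- base[, classIdx, drop = FALSE] *
    rep(tic, each = length(axis)) +
    abs(matrix(stats::rnorm(length(axis) * np, 0, config$baselineSigma),
               length(axis), np))

  dataset <- MSIDataset(mz = axis, intensity = intensity,
                        nX = config$nX, nY = config$nY,
                        pitchX = config$pitchX, pitchY = config$pitchY,
                        polarity = config$polarity,
                        matrixLabel = config$matrixLabel,
                        settingLabel = config$preset,
                        mzRange = config$mzRange)
  mk <- panel[panel$isMarker, ]
  enriched <- rbind(
    if (nrow(mk)) data.frame(mz = mk$mz, cellType = "RBC",
                             factor = mk$rbcFactor,
                             direction = sign(log(mk$rbcFactor))),
    if (nrow(mk)) data.frame(mz = mk$mz, cellType = "WBC",
                             factor = mk$wbcFactor,
                             direction = sign(log(mk$wbcFactor))))
  enriched <- enriched[enriched$direction != 0, , drop = FALSE]
  rownames(enriched) <- NULL
  list(dataset = dataset, roiSet = roiSet,
       truth = list(pixelClass = pix$label, cells = cells,
                    enriched = enriched, panel = panel))
}

#' Generate a multi-donor synthetic study
#'
#' Replicates [generateSmear()] across donors, with a per-(donor, peak)
#' log-normal amplitude multiplier as a donor random effect so that
#' cross-donor variance exists. The peak panel (peak positions and base
#' amplitudes) is built once, so features align across donors. In null mode
#' the donor random effect is disabled along with all enrichment: the null
#' study is fully exchangeable between cell and plasma ROIs.
#'
#' @param config A [smearSimConfig()].
#' @param nDonors Number of donors (>= 2; the study design uses 6).
#' @return A list of class `SmearStudy` with elements `smears` (list of
#'   [generateSmear()] outputs, one per donor), `config`, `panel`.
#' @examples
#' study <- generateStudy(smearSimConfig(nX = 12L, nY = 12L, seed = 5),
#'                        nDonors = 2L)
#' length(study$smears)
#' @export
generateStudy <- function(config, nDonors = 6L) {
  stopifnot(inherits(config, "SmearSimConfig"))
  if (nDonors < 2L)
    stop("differential analysis needs replication: nDonors must be >= 2")
  set.seed(config$seed)
  panel <- .buildPeakPanel(config)
  donorSeeds <- sample.int(2^30, nDonors)
  sdlog <- if (config$nullMode) 0 else config$donorSdlog
  donorMult <- matrix(stats::rlnorm(nrow(panel) * nDonors, 0, sdlog),
                      nrow(panel), nDonors)
  smears <- lapply(seq_len(nDonors), function(d)
    generateSmear(config, panel = panel, donorMult = donorMult[, d],
                  donor = d, smear = 1L, seed = donorSeeds[d]))
  structure(list(smears = smears, config = config, panel = panel),
            class = "SmearStudy")
}
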