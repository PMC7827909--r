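#' IonImage: lateral distribution of one m/z window
#'
#' A 2-D image of TIC-normalized intensity summed over an m/z tolerance
#' window, one value per pixel of the source grid (row `j`, column `i`).
#'
#' @slot values numeric matrix, `nY` rows by `nX` columns.
#' @slot targetMz Target m/z (Da).
#' @slot tol Tolerance (Da); the window is `|mz - target| <= tol`.
#' @slot pitchX,pitchY Pixel pitch carried from the source dataset (um).
#'
#' @aliases IonImage
#' @exportClass IonImage
setClass("IonImage", representation(
  values = "matrix", targetMz = "numeric", tol = "numeric",
  pitchX = "numeric", pitchY = "numeric"))

setValidity("IonImage", function(object) {
  if (anyNA(object@values) || (length(object@values) &&
      min(object@values) < 0))
    return("image values must be finite and >= 0")
  TRUE
})

setMethod("show", "IonImage", function(object) {
  cat(sprintf("IonImage: m/z %.5f +- %g Da, %d x %d px, range [%g, %g]\n",
              object@targetMz, object@tol, ncol(object@values),
              nrow(object@values), min(object@values), max(object@values)))
})

#' @describeIn ionImage Image values as an `nY` by `nX` matrix.
#' @export
imageValues <- function(image) image@values

#' Extract an ion image at a target m/z
#'
#' Per pixel, the image intensity is the sum of that pixel's TIC-normalized
#' intensities at m/z within `|mz - target| <= tol` (inclusive bounds, the
#' same tolerance semantics as metabolite annotation). Pixels with an all-zero
#' spectrum get intensity 0.
#'
#' @param dataset An [MSIDataset-class].
#' @param targetMz Target m/z (Da); must lie within the acquisition range.
#' @param tol Half-width of the extraction window (Da), default 0.025.
#' @param normalize TIC-normalize each pixel before extraction (default
#'   `TRUE`).
#' @param image An [IonImage-class].
#' @return An [IonImage-class].
#' @examples
#' sim <- generateSmear(smearSimConfig(nX = 10L, nY = 10L, seed = 2))
#' img <- ionImage(sim$dataset, sim$truth$panel$mz[1])
#' img
#' @export
ionImage <- function(dataset, targetMz, tol = 0.025, normalize = TRUE) {
  stopifnot(is(dataset, "MSIDataset"), tol >= 0)
  rng <- mzRange(dataset)
  if (targetMz < rng[1] || targetMz > rng[2])
    stop(sprintf("target m/z %.5f outside acquisition range %g-%g",
                 targetMz, rng[1], rng[2]))
  np <- nPixels(dataset)
  if (isContinuous(dataset)) {
    inWin <- abs(dataset@mz - targetMz) <= tol
    v <- colSums(dataset@intensity[inWin, , drop = FALSE])
    if (normalize) {
      tic <- colSums(dataset@intensity)
      v <- ifelse(tic > 0, v / tic, 0)
    }
  } else {
    v <- vapply(seq_len(np), function(k) {
      sp <- getSpectrum(dataset, k)
      tic <- sum(sp$intensity)
      w <- sum(sp$intensity[abs(sp$mz - targetMz) <= tol])
      if (normalize) { if (tic > 0) w / tic else 0 } else w
    }, numeric(1))
  }
  new("IonImage",
      values = matrix(v, nrow = dataset@nY, ncol = dataset@nX, byrow = TRUE),
      targetMz = targetMz, tol = tol,
      pitchX = dataset@pitchX, pitchY = dataset@pitchY)
}

# reflect 1-based indices into 1..n (half-sample symmetric reflection)
.reflectIndex <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  m <- ((idx - 1L) %% period + period) %% period
  ifelse(m < n, m + 1L, period - m)
}

#' Median-smooth an ion image
#'
#' Replaces each pixel by the median of its `kernel` by `kernel`
#' neighborhood; edges are handled by reflection. `kernel = 1` is the
#' identity. The output never leaves the input's value range.
#'
#' @param image An [IonImage-class] (or plain matrix).
#' @param kernel Odd window size >= 1 (default 3).
#' @return Same type as the input.
#' @export
medianSmooth <- function(image, kernel = 3L) {
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("'kernel' must be an odd integer >= 1")
  m <- if (is(image, "IonImage")) image@values else image
  if (kernel > 1L) {
    r <- (kernel - 1L) %/% 2L
    nr <- nrow(m); nc <- ncol(m)
    stack <- array(NA_real_, c(nr, nc, kernel * kernel))
    s <- 0L
    for (dy in -r:r) for (dx in -r:r) {
      s <- s + 1L
      stack[, , s] <- m[.reflectIndex(seq_len(nr) + dy, nr),
                        .reflectIndex(seq_len(nc) + dx, nc)]
    }
    m <- apply(stack, c(1L, 2L), stats::median)
  }
  if (is(image, "IonImage")) { image@values <- m; image } else m
}

# Lanczos kernel, support |x| < a
.lanczosKernel <- function(x, a) {
  out <- numeric(length(x))
  nz <- abs(x) < a & x != 0
  out[x == 0] <- 1
  out[nz] <- a * sin(pi * x[nz]) * sin(pi * x[nz] / a) / (pi^2 * x[nz]^2)
  out
}

# m x n weight matrix resampling a length-n signal to length m = n * factor
.lanczosWeights <- function(n, factor, a) {
  m <- n * factor
  u <- seq_len(m) - 1L
  x <- (u + 0.5) / factor - 0.5          # source coordinate, 0-based
  lo <- floor(x) - a + 1
  W <- matrix(0, m, n)
  for (t in 0:(2 * a - 1)) {
    src <- lo + t
    w <- .lanczosKernel(x - src, a)
    idx <- .reflectIndex(as.integer(src) + 1L, n)
    W[cbind(seq_len(m), idx)] <- W[cbind(seq_len(m), idx)] + w
  }
  W / rowSums(W)
}

#' Upsample an ion image by Lanczos interpolation
#'
#' Separable Lanczos-`a` resampling to an integer multiple of the grid size,
#' for display. Edges are reflection-padded, the kernel weights are
#' normalized per output pixel, and (since Lanczos lobes can undershoot)
#' the result is clipped at 0. `factor = 1` is the identity.
#'
#' @param image An [IonImage-class] (or plain matrix).
#' @param factor Integer upsampling factor >= 1.
#' @param a Lanczos kernel order (default 3).
#' @return Same type as the input, with `factor`-times the rows and columns.
#' @export
lanczosUpsample <- function(image, factor, a = 3L) {
  if (factor < 1L || factor != round(factor))
    stop("'factor' must be an integer >= 1")
  m <- if (is(image, "IonImage")) image@values else image
  if (factor > 1L) {
    Wr <- .lanczosWeights(nrow(m), factor, a)
    Wc <- .lanczosWeights(ncol(m), factor, a)
    m <- Wr %*% m %*% t(Wc)
    m[m < 0] <- 0
  }
  if (is(image, "IonImage")) {
    image@values <- m
    image@pitchX <- image@pitchX / factor
    image@pitchY <- image@pitchY / factor
    image
  } else m
}

#' Export an ion image overlaid on a cell label map
#'
#' Renders the ion image as a heat colormap alpha-blended over a synthetic
#' cell map (RBC red, WBC light blue, plasma pale yellow) and writes a PNG.
#' The label map is nearest-neighbor-scaled to the image dimensions when
#' needed. Colormap bounds are fixed by the image minimum and maximum, so
#' re-rendering identical inputs gives a byte-identical file.
#'
#' @param image An [IonImage-class] or matrix of intensities.
#' @param cellLabelMap Character matrix (`nY` by `nX`) of pixel classes
#'   (`RBC`, `WBC`, `plasma`), e.g. the simulator truth reshaped; or `NULL`
#'   for a plain black background.
#' @param path Output PNG path.
#' @param maxAlpha Peak opacity of the intensity layer (default 0.85).
#' @return Invisibly, `path`.
#' @export
overlayExport <- function(image, cellLabelMap, path, maxAlpha = 0.85) {
  v <- if (is(image, "IonImage")) image@values else image
  nr <- nrow(v); nc <- ncol(v)
  baseCols <- c(RBC = "#B22222", WBC = "#ADD8E6", plasma = "#FFF7DC")
  if (is.null(cellLabelMap)) {
    base <- array(0, c(nr, nc, 3L))
  } else {
    lab <- as.matrix(cellLabelMap)
    ri <- .reflectIndex(ceiling(seq_len(nr) * nrow(lab) / nr), nrow(lab))
    ci <- .reflectIndex(ceiling(seq_len(nc) * ncol(lab) / nc), ncol(lab))
    lab <- lab[ri, ci, drop = FALSE]
    rgb <- grDevices::col2rgb(baseCols[lab]) / 255
    base <- array(0, c(nr, nc, 3L))
    for (ch in 1:3) base[, , ch] <- matrix(rgb[ch, ], nr, nc)
  }
  rngv <- range(v)
  alpha <- if (diff(rngv) > 0) (v - rngv[1]) / diff(rngv)
           else matrix(0, nr, nc)
  ramp <- grDevices::colorRamp(
    grDevices::hcl.colors(256L, "Inferno"), space = "rgb")
  heat <- ramp(as.vector(alpha)) / 255
  out <- array(0, c(nr, nc, 3L))
  for (ch in 1:3)
    out[, , ch] <- (1 - maxAlpha * alpha) * base[, , ch] +
      maxAlpha * alpha * matrix(heat[, ch], nr, nc)
  png::writePNG(out, target = path)
  invisible(path)
}
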