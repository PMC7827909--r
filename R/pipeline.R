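#' Study-level ROI sample table over a common feature space
#'
#' Builds, for a multi-donor study, one ROI-by-feature table over a single
#' feature space shared by all donors: every donor's dataset is preprocessed
#' on the same 0.020 Da bin grid (TIC normalization, binning,
#' relative-intensity threshold, no per-donor cap), then bins are ranked by
#' their pooled mean TIC-normalized intensity over all donors' pixels and the
#' top `topK` are kept. This keeps the published per-set feature cap while
#' giving every feature data in every donor; a feature that fell below a
#' donor's threshold is zero in that donor's ROIs.
#'
#' @param study A `SmearStudy` from [generateStudy()], or a list of
#'   per-donor lists with elements `dataset` and `roiSet`.
#' @param binWidth,thresholdFraction,thresholdPerPixel Passed to
#'   [buildFeatureMatrix()].
#' @param topK Study-level feature cap (default 500).
#' @return A [ROISampleTable-class] whose rows span all donors' ROIs.
#' @export
studyRoiTable <- function(study, binWidth = 0.020,
                          thresholdFraction = 0.001, topK = 500L,
                          thresholdPerPixel = FALSE) {
  smears <- if (inherits(study, "SmearStudy")) study$smears else study
  stopifnot(length(smears) >= 2L)
  pms <- lapply(smears, function(s)
    buildFeatureMatrix(s$dataset, binWidth = binWidth,
                       thresholdFraction = thresholdFraction,
                       thresholdPerPixel = thresholdPerPixel, topK = Inf))
  rts <- lapply(seq_along(smears), function(d)
    aggregateRois(pms[[d]], smears[[d]]$roiSet, smears[[d]]$dataset))

  bins <- lapply(pms, function(p) rowData(p)$bin)
  union <- sort(unique(unlist(bins)))
  nd <- length(pms)
  score <- wmz <- wsum <- numeric(length(union))
  npixTot <- 0L
  for (d in seq_len(nd)) {
    r <- match(bins[[d]], union)
    a <- assay(pms[[d]])
    npx <- ncol(a)
    score[r] <- score[r] + rowSums(a)
    tot <- rowSums(a)
    wmz[r] <- wmz[r] + rowData(pms[[d]])$mz * tot
    wsum[r] <- wsum[r] + tot
    npixTot <- npixTot + npx
  }
  score <- score / npixTot                      # pooled mean per bin
  mzUnion <- ifelse(wsum > 0, wmz / wsum, NA_real_)
  ord <- order(-score, mzUnion)
  keep <- sort(ord[seq_len(min(topK, length(union)))])
  union <- union[keep]
  mzUnion <- mzUnion[keep]

  rows <- lapply(seq_len(nd), function(d) {
    v <- matrix(0, nrow(roiValues(rts[[d]])), length(union))
    r <- match(bins[[d]], union)
    has <- !is.na(r)
    v[, r[has]] <- roiValues(rts[[d]])[, has, drop = FALSE]
    v
  })
  info <- do.call(rbind, lapply(rts, roiInfo))
  new("ROISampleTable", values = do.call(rbind, rows), roiInfo = info,
      mz = mzUnion, labels = rts[[1]]@labels)
}

#' Pipeline configuration
#'
#' Assembles all stage parameters of the end-to-end analysis with the
#' published defaults: 0.020 Da bins, 0.1% relative intensity threshold,
#' top-500 features, 0.05 significance limit, 0.025 Da annotation and
#' ion-image tolerance. One seed governs all stochastic stages (stage seeds
#' are derived from it by a fixed scheme).
#'
#' @param preset,mode,nX,nY,... Simulation parameters forwarded to
#'   [smearSimConfig()].
#' @param ranges List of m/z ranges acquired per smear (default the two
#'   neighboring ranges 200-600 and 600-900 Da).
#' @param nDonors Number of donors (default 6).
#' @param binWidth,thresholdFraction,topK,alpha,tol The published analysis
#'   parameters.
#' @param seed Master RNG seed.
#' @param outDir Output directory for [runPipeline()].
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(preset = "D1", mode = "CHCA-positive",
                           nX = 20L, nY = 20L,
                           ranges = list(c(200, 600), c(600, 900)),
                           nDonors = 6L,
                           binWidth = 0.020, thresholdFraction = 0.001,
                           topK = 500L, alpha = 0.05, tol = 0.025,
                           seed = 1L, outDir = tempfile("smearmsi-run-"),
                           ...) {
  stopifnot(binWidth > 0, alpha >= 0, alpha <= 1, tol > 0, topK >= 1)
  structure(list(preset = preset, mode = mode, nX = as.integer(nX),
                 nY = as.integer(nY), ranges = ranges,
                 nDonors = as.integer(nDonors), binWidth = binWidth,
                 thresholdFraction = thresholdFraction,
                 topK = as.integer(topK), alpha = alpha, tol = tol,
                 seed = as.integer(seed), outDir = outDir,
                 simArgs = list(...)), class = "PipelineConfig")
}

#' Run the full blood-smear MSI analysis pipeline
#'
#' Orchestrates simulate, preprocess, differential testing, annotation and
#' ion-image rendering as one reproducible run: for each m/z range a
#' multi-donor study is generated, preprocessed into a common feature space
#' ([studyRoiTable()]), tested per cell type against plasma, and the
#' significant m/z of all ranges are annotated against the bundled (or
#' user-supplied) metabolite database. Marker ion images of the first
#' donor's smear are rendered with median smoothing, Lanczos upsampling and
#' a cell-map overlay. All tables, ROI/truth JSON files, images and a
#' manifest (parameters, versions, output checksums) are written under
#' `config$outDir`; reruns with the same config are byte-identical.
#'
#' @param config A [pipelineConfig()].
#' @param db Metabolite table (default the bundled database).
#' @param writeImzml Also export each donor dataset as imzML (default
#'   `FALSE`; the files are large).
#' @return Invisibly, a list: `diffTables`, `counts`, `annotations`,
#'   `roiTables`, `studies`, `truthHits`, `manifest`.
#' @examples
#' \donttest{
#' res <- runPipeline(pipelineConfig(nX = 14L, nY = 14L, nDonors = 3L,
#'                                   ranges = list(c(600, 900)), seed = 11))
#' res$counts
#' }
#' @export
runPipeline <- function(config, db = readMetaboliteTable(bundledMetaboliteDb()),
                        writeImzml = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$outDir, "images"), showWarnings = FALSE)

  set.seed(config$seed)
  rangeSeeds <- sample.int(2^30, length(config$ranges))

  studies <- list(); roiTables <- list(); diffTables <- list()
  for (ri in seq_along(config$ranges)) {
    rng <- config$ranges[[ri]]
    cfg <- do.call(smearSimConfig, c(
      list(preset = config$preset, mode = config$mode, nX = config$nX,
           nY = config$nY, mzRange = rng, seed = rangeSeeds[ri]),
      config$simArgs))
    study <- generateStudy(cfg, nDonors = config$nDonors)
    rt <- studyRoiTable(study, binWidth = config$binWidth,
                        thresholdFraction = config$thresholdFraction,
                        topK = config$topK)
    studies[[ri]] <- study
    roiTables[[ri]] <- rt
    for (ct in c("RBC", "WBC")) {
      dt <- differentialTable(rt, ct, alpha = config$alpha)
      dt$rangeLow <- rng[1]
      diffTables[[length(diffTables) + 1L]] <- dt
    }
    sm1 <- study$smears[[1]]
    writeRoiJson(sm1$roiSet,
                 file.path(config$outDir, sprintf("rois_range%d.json", ri)))
    jsonlite::write_json(
      list(pixelClass = sm1$truth$pixelClass,
           enriched = sm1$truth$enriched),
      file.path(config$outDir, sprintf("truth_range%d.json", ri)),
      auto_unbox = TRUE, digits = NA)
    if (writeImzml)
      for (d in seq_along(study$smears))
        writeImzML(study$smears[[d]]$dataset,
                   file.path(config$outDir,
                             sprintf("donor%d_range%d.imzML", d, ri)))
    # marker ion images of the first donor's smear
    mk <- cfg$markers
    for (mi in seq_len(nrow(mk))) {
      img <- ionImage(sm1$dataset, mk$mz[mi], tol = config$tol)
      img <- medianSmooth(img, 3L)
      img <- lanczosUpsample(img, 4L)
      labmap <- matrix(sm1$truth$pixelClass, nrow = config$nY,
                       ncol = config$nX, byrow = TRUE)
      overlayExport(img, labmap,
                    file.path(config$outDir, "images",
                              sprintf("mz%.3f_range%d.png", mk$mz[mi], ri)))
    }
  }

  counts <- countSignificant(diffTables)
  annos <- do.call(rbind, lapply(diffTables, annotateDiffTable, db = db,
                                 tol = config$tol))

  # truth-vs-found: which truly enriched markers were recovered
  truthHits <- do.call(rbind, lapply(seq_along(config$ranges), function(ri) {
    truth <- studies[[ri]]$smears[[1]]$truth$enriched
    if (!nrow(truth)) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(truth)), function(k) {
      dts <- Filter(function(d) d$rangeLow[1] == config$ranges[[ri]][1] &&
                      d$cellType[1] == truth$cellType[k], diffTables)
      dt <- dts[[1]]
      f <- which.min(abs(dt$mz - truth$mz[k]))
      found <- abs(dt$mz[f] - truth$mz[k]) <= config$tol &&
        dt$significant[f] &&
        sign(log(dt$foldChange[f])) == truth$direction[k]
      data.frame(mz = truth$mz[k], cellType = truth$cellType[k],
                 factor = truth$factor[k], recovered = found)
    }))
  }))

  for (i in seq_along(diffTables)) {
    dt <- diffTables[[i]]
    utils::write.csv(dt, file.path(config$outDir,
      sprintf("diff_%s_%d.csv", dt$cellType[1], dt$rangeLow[1])),
      row.names = FALSE)
  }
  utils::write.csv(counts, file.path(config$outDir, "diff_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(annos, file.path(config$outDir, "annotations.csv"),
                   row.names = FALSE)
  if (!is.null(truthHits))
    utils::write.csv(truthHits, file.path(config$outDir, "truth_found.csv"),
                     row.names = FALSE)

  paramPath <- file.path(config$outDir, "params.json")
  jsonlite::write_json(config[setdiff(names(config), "outDir")], paramPath,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  outputs <- setdiff(list.files(config$outDir, recursive = TRUE),
                     "manifest.json")
  manifest <- list(
    package = "smearMSI",
    version = as.character(utils::packageVersion("smearMSI")),
    rversion = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameterHash = unname(tools::md5sum(paramPath)),
    outputs = as.list(tools::md5sum(file.path(config$outDir, outputs))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(diffTables = diffTables, counts = counts,
                 annotations = annos, roiTables = roiTables,
                 studies = studies, truthHits = truthHits,
                 manifest = manifest))
}
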