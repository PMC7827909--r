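#' imzML input and output
#'
#' Reads and writes MSI datasets in the imzML interchange format: an XML
#' metadata file (`.imzML`) plus a binary array file (`.ibd`) referenced by
#' external byte offsets. Both binary layouts are supported: continuous (one
#' shared m/z axis stored once) and processed (per-pixel m/z axes).
#'
#' The writer stores all arrays as uncompressed 64-bit floats and records the
#' pixel grid (max pixel counts, pixel size), ionization polarity and per-
#' spectrum positions with the standard imaging-MS controlled-vocabulary
#' accessions, so files interoperate with the usual imzML readers.
#'
#' @name imzml-io
NULL

.IMZML_NS <- "http://psi.hupo.org/ms/mzml"

.randomUUIDBytes <- function() {
  b <- as.raw(sample(0:255, 16L, replace = TRUE))
  b[7] <- as.raw(bitwOr(bitwAnd(as.integer(b[7]), 0x0F), 0x40))  # version 4
  b[9] <- as.raw(bitwOr(bitwAnd(as.integer(b[9]), 0x3F), 0x80))  # variant
  b
}

.uuidToString <- function(bytes) {
  h <- format(bytes)
  paste0(paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
         paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
         paste(h[11:16], collapse = ""))
}

.cvParam <- function(parent, cvRef, accession, name, value = "",
                     unitAccession = NULL, unitName = NULL, unitCvRef = NULL) {
  node <- xml2::xml_add_child(parent, "cvParam", cvRef = cvRef,
                              accession = accession, name = name,
                              value = as.character(value))
  if (!is.null(unitAccession)) {
    xml2::xml_set_attr(node, "unitCvRef", unitCvRef)
    xml2::xml_set_attr(node, "unitAccession", unitAccession)
    xml2::xml_set_attr(node, "unitName", unitName)
  }
  node
}

#' Write an MSIDataset to imzML
#'
#' @param dataset An [MSIDataset-class].
#' @param path Output path for the `.imzML` file; the `.ibd` file is written
#'   alongside with the same stem.
#' @return Invisibly, the `.imzML` path.
#' @seealso [readImzML()]
#' @export
writeImzML <- function(dataset, path) {
  stopifnot(is(dataset, "MSIDataset"))
  path <- normalizePath(path, mustWork = FALSE)
  ibdPath <- paste0(tools::file_path_sans_ext(path), ".ibd")
  continuous <- isContinuous(dataset)
  np <- nPixels(dataset)
  uuid <- .randomUUIDBytes()

  ## ---- binary part ----
  con <- file(ibdPath, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  # per spectrum: mz offset/length, intensity offset/length
  mzOff <- mzLen <- intOff <- intLen <- numeric(np)
  if (continuous) {
    ax <- dataset@mz
    writeBin(ax, con, size = 8, endian = "little")
    sharedOff <- offset
    offset <- offset + 8 * length(ax)
    for (k in seq_len(np)) {
      v <- dataset@intensity[, k]
      writeBin(as.numeric(v), con, size = 8, endian = "little")
      mzOff[k] <- sharedOff; mzLen[k] <- length(ax)
      intOff[k] <- offset; intLen[k] <- length(v)
      offset <- offset + 8 * length(v)
    }
  } else {
    for (k in seq_len(np)) {
      mzk <- dataset@spectraMz[[k]]
      ik <- dataset@spectraIntensity[[k]]
      writeBin(as.numeric(mzk), con, size = 8, endian = "little")
      mzOff[k] <- offset; mzLen[k] <- length(mzk)
      offset <- offset + 8 * length(mzk)
      writeBin(as.numeric(ik), con, size = 8, endian = "little")
      intOff[k] <- offset; intLen[k] <- length(ik)
      offset <- offset + 8 * length(ik)
    }
  }

  ## ---- XML part ----
  doc <- xml2::xml_new_root("mzML", xmlns = .IMZML_NS, version = "1.1")
  cvl <- xml2::xml_add_child(doc, "cvList", count = "3")
  xml2::xml_add_child(cvl, "cv", id = "MS",
    fullName = "Proteomics Standards Initiative Mass Spectrometry Ontology",
    URI = "https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo")
  xml2::xml_add_child(cvl, "cv", id = "UO", fullName = "Unit Ontology",
    URI = "https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo")
  xml2::xml_add_child(cvl, "cv", id = "IMS", fullName = "Imaging MS Ontology",
    URI = "https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo")
  fd <- xml2::xml_add_child(doc, "fileDescription")
  fc <- xml2::xml_add_child(fd, "fileContent")
  .cvParam(fc, "MS", "MS:1000579", "MS1 spectrum")
  if (continuous) .cvParam(fc, "IMS", "IMS:1000030", "continuous")
  else .cvParam(fc, "IMS", "IMS:1000031", "processed")
  .cvParam(fc, "IMS", "IMS:1000080", "universally unique identifier",
           paste0("{", .uuidToString(uuid), "}"))

  rpgl <- xml2::xml_add_child(doc, "referenceableParamGroupList", count = "2")
  rgm <- xml2::xml_add_child(rpgl, "referenceableParamGroup", id = "mzArray")
  .cvParam(rgm, "MS", "MS:1000514", "m/z array",
           unitCvRef = "MS", unitAccession = "MS:1000040", unitName = "m/z")
  .cvParam(rgm, "MS", "MS:1000523", "64-bit float")
  .cvParam(rgm, "MS", "MS:1000576", "no compression")
  .cvParam(rgm, "IMS", "IMS:1000101", "external data", "true")
  rgi <- xml2::xml_add_child(rpgl, "referenceableParamGroup",
                             id = "intensityArray")
  .cvParam(rgi, "MS", "MS:1000515", "intensity array",
           unitCvRef = "MS", unitAccession = "MS:1000131",
           unitName = "number of detector counts")
  .cvParam(rgi, "MS", "MS:1000523", "64-bit float")
  .cvParam(rgi, "MS", "MS:1000576", "no compression")
  .cvParam(rgi, "IMS", "IMS:1000101", "external data", "true")

  swl <- xml2::xml_add_child(doc, "softwareList", count = "1")
  sw <- xml2::xml_add_child(swl, "software", id = "smearMSI",
                            version = as.character(utils::packageVersion("smearMSI")))
  .cvParam(sw, "MS", "MS:1000799", "custom unreleased software tool", "smearMSI")

  ssl <- xml2::xml_add_child(doc, "scanSettingsList", count = "1")
  ss <- xml2::xml_add_child(ssl, "scanSettings", id = "scansettings1")
  .cvParam(ss, "IMS", "IMS:1000042", "max count of pixels x", dataset@nX)
  .cvParam(ss, "IMS", "IMS:1000043", "max count of pixels y", dataset@nY)
  .cvParam(ss, "IMS", "IMS:1000046", "pixel size (x)", dataset@pitchX,
           unitCvRef = "UO", unitAccession = "UO:0000017",
           unitName = "micrometer")
  .cvParam(ss, "IMS", "IMS:1000047", "pixel size (y)", dataset@pitchY,
           unitCvRef = "UO", unitAccession = "UO:0000017",
           unitName = "micrometer")

  icl <- xml2::xml_add_child(doc, "instrumentConfigurationList", count = "1")
  xml2::xml_add_child(icl, "instrumentConfiguration", id = "IC1")
  dpl <- xml2::xml_add_child(doc, "dataProcessingList", count = "1")
  dp <- xml2::xml_add_child(dpl, "dataProcessing", id = "export")
  pm <- xml2::xml_add_child(dp, "processingMethod", order = "1",
                            softwareRef = "smearMSI")
  .cvParam(pm, "MS", "MS:1000544", "Conversion to mzML")

  run <- xml2::xml_add_child(doc, "run", defaultInstrumentConfigurationRef = "IC1",
                             id = "run1")
  spl <- xml2::xml_add_child(run, "spectrumList", count = as.character(np),
                             defaultDataProcessingRef = "export")
  pc <- pixelCoords(dataset)
  polAcc <- if (dataset@polarity == "negative")
    c("MS:1000129", "negative scan") else c("MS:1000130", "positive scan")
  for (k in seq_len(np)) {
    sp <- xml2::xml_add_child(spl, "spectrum",
                              id = sprintf("spectrum=%d", k),
                              index = as.character(k - 1L),
                              defaultArrayLength = "0")
    .cvParam(sp, "MS", polAcc[1], polAcc[2])
    scl <- xml2::xml_add_child(sp, "scanList", count = "1")
    .cvParam(scl, "MS", "MS:1000795", "no combination")
    sc <- xml2::xml_add_child(scl, "scan")
    .cvParam(sc, "IMS", "IMS:1000050", "position x", pc$i[k] + 1L)
    .cvParam(sc, "IMS", "IMS:1000051", "position y", pc$j[k] + 1L)
    bdal <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")
    bm <- xml2::xml_add_child(bdal, "binaryDataArray", encodedLength = "0")
    xml2::xml_add_child(bm, "referenceableParamGroupRef", ref = "mzArray")
    .cvParam(bm, "IMS", "IMS:1000103", "external array length", mzLen[k])
    .cvParam(bm, "IMS", "IMS:1000104", "external encoded length", 8 * mzLen[k])
    .cvParam(bm, "IMS", "IMS:1000102", "external offset", mzOff[k])
    xml2::xml_add_child(bm, "binary")
    bi <- xml2::xml_add_child(bdal, "binaryDataArray", encodedLength = "0")
    xml2::xml_add_child(bi, "referenceableParamGroupRef", ref = "intensityArray")
    .cvParam(bi, "IMS", "IMS:1000103", "external array length", intLen[k])
    .cvParam(bi, "IMS", "IMS:1000104", "external encoded length", 8 * intLen[k])
    .cvParam(bi, "IMS", "IMS:1000102", "external offset", intOff[k])
    xml2::xml_add_child(bi, "binary")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# read one external array from an open ibd connection
.readIbdArray <- function(con, ibdSize, offset, n, bytes, pixel, what) {
  if (offset + n * bytes > ibdSize)
    stop(sprintf(
      "truncated .ibd: %s array of pixel %d needs bytes %d-%d but file has %d",
      what, pixel, offset, offset + n * bytes, ibdSize), call. = FALSE)
  seek(con, where = offset, origin = "start")
  readBin(con, "double", n = n, size = bytes, endian = "little")
}

.paramAccessions <- function(node) {
  xml2::xml_attr(xml2::xml_find_all(node, "./cvParam"), "accession")
}

#' Read an imzML file
#'
#' @param path Path to the `.imzML` file; the `.ibd` file must sit alongside.
#' @param pitchX,pitchY Fallback pixel pitch (um) when the file carries no
#'   pixel-size metadata.
#' @param matrixLabel,settingLabel Acquisition labels not represented in
#'   imzML; taken from these arguments.
#' @return An [MSIDataset-class]; processed-mode files yield a dataset flagged
#'   non-uniform (`isContinuous()` is `FALSE`).
#' @seealso [writeImzML()]
#' @export
readImzML <- function(path, pitchX = NULL, pitchY = NULL,
                      matrixLabel = "9AA", settingLabel = "D0") {
  ibdPath <- paste0(tools::file_path_sans_ext(path), ".ibd")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(ibdPath)) stop("missing binary file: ", ibdPath)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  fcAcc <- .paramAccessions(xml2::xml_find_first(doc, ".//fileContent"))
  continuous <- "IMS:1000030" %in% fcAcc
  if (!continuous && !"IMS:1000031" %in% fcAcc)
    stop("imzML file declares neither continuous nor processed binary mode")

  # referenceable param groups: which ids mean m/z, which intensity; precision
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  groupRole <- groupBytes <- character(0)
  for (g in groups) {
    acc <- .paramAccessions(g)
    id <- xml2::xml_attr(g, "id")
    role <- if ("MS:1000514" %in% acc) "mz"
            else if ("MS:1000515" %in% acc) "intensity" else NA_character_
    bytes <- if ("MS:1000523" %in% acc) "8"
             else if ("MS:1000521" %in% acc) "4" else "8"
    groupRole[id] <- role
    groupBytes[id] <- bytes
  }

  ssNode <- xml2::xml_find_first(doc, ".//scanSettings")
  getSS <- function(acc) {
    v <- xml2::xml_attr(xml2::xml_find_first(
      ssNode, sprintf("./cvParam[@accession='%s']", acc)), "value")
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  nX <- getSS("IMS:1000042"); nY <- getSS("IMS:1000043")
  px <- getSS("IMS:1000046"); py <- getSS("IMS:1000047")
  if (!is.na(px)) pitchX <- px
  if (!is.na(py)) pitchY <- py
  if (is.null(pitchX)) pitchX <- 8
  if (is.null(pitchY)) pitchY <- 7

  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  np <- length(spectra)
  if (!np) stop("imzML file contains no spectra")

  ibdSize <- file.info(ibdPath)$size
  con <- file(ibdPath, "rb")
  on.exit(close(con), add = TRUE)

  posX <- posY <- integer(np)
  mzList <- intList <- vector("list", np)
  polarity <- "negative"
  for (k in seq_len(np)) {
    sp <- spectra[[k]]
    spAcc <- .paramAccessions(sp)
    if ("MS:1000130" %in% spAcc) polarity <- "positive"
    scan <- xml2::xml_find_first(sp, ".//scan")
    getScan <- function(acc) as.integer(xml2::xml_attr(xml2::xml_find_first(
      scan, sprintf("./cvParam[@accession='%s']", acc)), "value"))
    posX[k] <- getScan("IMS:1000050")
    posY[k] <- getScan("IMS:1000051")
    if (is.na(posX[k]) || is.na(posY[k]))
      stop("spectrum ", k, " carries no pixel position")
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "./referenceableParamGroupRef"), "ref")
      acc <- .paramAccessions(bda)
      role <- if (!is.na(ref) && !is.na(groupRole[ref])) groupRole[[ref]]
              else if ("MS:1000514" %in% acc) "mz"
              else if ("MS:1000515" %in% acc) "intensity" else NA_character_
      if (is.na(role)) next
      bytes <- as.integer(
        if (!is.na(ref) && ref %in% names(groupBytes)) groupBytes[[ref]]
        else if ("MS:1000521" %in% acc) "4" else "8")
      getB <- function(a) as.numeric(xml2::xml_attr(xml2::xml_find_first(
        bda, sprintf("./cvParam[@accession='%s']", a)), "value"))
      off <- getB("IMS:1000102"); len <- getB("IMS:1000103")
      if (is.na(off) || is.na(len))
        stop("spectrum ", k, ": binary array lacks external offset/length")
      v <- .readIbdArray(con, ibdSize, off, len, bytes, k, role)
      if (role == "mz") mzList[[k]] <- v else intList[[k]] <- v
    }
    if (is.null(mzList[[k]]) || is.null(intList[[k]]))
      stop("spectrum ", k, ": missing m/z or intensity array")
  }

  if (is.na(nX)) nX <- max(posX)
  if (is.na(nY)) nY <- max(posY)
  pixel <- (posX - 1L) + (posY - 1L) * as.integer(nX) + 1L
  ord <- order(pixel)
  if (any(duplicated(pixel)))
    stop("duplicate pixel positions in imzML file")
  if (length(pixel) != nX * nY)
    stop(sprintf("grid is %dx%d but file has %d spectra", nX, nY, np))

  if (continuous) {
    ax <- mzList[[ord[1]]]
    MSIDataset(mz = ax,
               intensity = do.call(cbind, intList[ord]),
               nX = nX, nY = nY, pitchX = pitchX, pitchY = pitchY,
               polarity = polarity, matrixLabel = matrixLabel,
               settingLabel = settingLabel)
  } else {
    MSIDataset(mz = mzList[ord], intensity = intList[ord],
               nX = nX, nY = nY, pitchX = pitchX, pitchY = pitchY,
               polarity = polarity, matrixLabel = matrixLabel,
               settingLabel = settingLabel)
  }
}
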