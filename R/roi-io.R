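#' Read and write ROI definition files
#'
#' ROI sets are serialized as JSON: an object with a `rois` array whose
#' elements carry `label`, `centerX`, `centerY`, `semiX`, `semiY` (um),
#' `rotation` (degrees), `donor` and `smear`. Unknown fields are preserved on
#' read.
#'
#' @param path File path.
#' @return `readRoiJson` returns a [ROISet-class]; `writeRoiJson` invisibly
#'   returns `path`.
#' @examples
#' rs <- ROISet(label = "RBC", centerX = 20, centerY = 14, semiX = 4,
#'              semiY = 3.5)
#' f <- tempfile(fileext = ".json")
#' writeRoiJson(rs, f)
#' readRoiJson(f)
#' @name roi-json
NULL

#' @rdname roi-json
#' @param roiSet A [ROISet-class].
#' @export
writeRoiJson <- function(roiSet, path) {
  stopifnot(is(roiSet, "ROISet"))
  jsonlite::write_json(list(format = "smearMSI-roi", version = 1L,
                            rois = rois(roiSet)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname roi-json
#' @export
readRoiJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- obj$rois
  if (is.null(df) || !is.data.frame(df))
    stop("ROI JSON must contain a 'rois' array of objects")
  missing <- setdiff(.ROI_COLUMNS, names(df))
  defaults <- list(rotation = 0, donor = 1L, smear = 1L)
  for (m in intersect(missing, names(defaults)))
    df[[m]] <- defaults[[m]]
  missing <- setdiff(.ROI_COLUMNS, names(df))
  if (length(missing))
    stop("ROI JSON missing required field(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), .ROI_COLUMNS)
  df <- df[, c(.ROI_COLUMNS, extra), drop = FALSE]
  new("ROISet", rois = df)
}

#' Read a metabolite mass table
#'
#' Reads a CSV/TSV metabolite table with the columns `kegg_id` (or a generic
#' `id`), `name`, `formula` (optional per record), `monoisotopic_mass` (Da)
#' and `endogenous_or_essential` (logical). An `hmdb_id` column is carried if
#' present, as are any extra columns. When a record has both a formula and a
#' mass, the two must agree within 1e-3 Da; records with a formula but no
#' mass get the mass computed from the formula.
#'
#' @param path File path; the delimiter is taken from the extension (`.tsv`
#'   uses tab, otherwise comma).
#' @return A data.frame of metabolite records.
#' @examples
#' db <- readMetaboliteTable(bundledMetaboliteDb())
#' nrow(db)
#' @export
readMetaboliteTable <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          check.names = TRUE)
  if (!"kegg_id" %in% names(df) && "id" %in% names(df))
    names(df)[names(df) == "id"] <- "kegg_id"
  required <- c("kegg_id", "name", "monoisotopic_mass",
                "endogenous_or_essential")
  hasFormula <- "formula" %in% names(df)
  if (hasFormula) {
    noMass <- !"monoisotopic_mass" %in% names(df)
    if (noMass) df$monoisotopic_mass <- NA_real_
    fill <- is.na(df$monoisotopic_mass) & nzchar(df$formula)
    if (any(fill))
      df$monoisotopic_mass[fill] <-
        vapply(df$formula[fill], monoisotopicMass, numeric(1))
  }
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metabolite table missing required column(s): ",
         paste(missing, collapse = ", "))
  df$monoisotopic_mass <- as.numeric(df$monoisotopic_mass)
  if (anyNA(df$monoisotopic_mass) || any(df$monoisotopic_mass <= 0))
    stop("all records need a positive monoisotopic mass")
  df$endogenous_or_essential <- as.logical(df$endogenous_or_essential)
  if (hasFormula) {
    check <- nzchar(df$formula) & !is.na(df$formula)
    calc <- vapply(df$formula[check], monoisotopicMass, numeric(1))
    bad <- abs(calc - df$monoisotopic_mass[check]) > 1e-3
    if (any(bad))
      stop("formula/mass disagreement > 1e-3 Da for record(s): ",
           paste(df$kegg_id[check][bad], collapse = ", "))
  }
  df
}

#' Bundled reference tables
#'
#' Paths to the plain-text reference tables shipped with the package: the
#' curated blood-smear metabolite database (distinct compounds from the
#' published differential-expression list plus the ATP/IMP/heme marker
#' compounds, with formulas curated from their KEGG entries), the published
#' differential m/z list itself, the cellular marker panel, the element mass
#' table and the adduct registry.
#'
#' @return A file path.
#' @name bundled-tables
NULL

.extdata <- function(file) {
  system.file("extdata", file, package = "smearMSI", mustWork = TRUE)
}

#' @rdname bundled-tables
#' @export
bundledMetaboliteDb <- function() .extdata("blood_metabolite_db.tsv")

#' @rdname bundled-tables
#' @export
bundledDiffMzTable <- function() .extdata("blood_smear_diff_mz.tsv")

#' @rdname bundled-tables
#' @export
bundledMarkerPanel <- function() .extdata("marker_panel.tsv")
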