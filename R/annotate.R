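#' Match an observed m/z against a metabolite database
#'
#' Exhaustive scan over all (metabolite, adduct rule) pairs: a pair is a hit
#' when `|observed - adductMz(mass, rule)| <= tol`. Hits are returned sorted
#' by absolute mass error.
#'
#' @param observedMz Observed m/z (Da), scalar.
#' @param db Metabolite table as from [readMetaboliteTable()] (columns
#'   `kegg_id`, `name`, `monoisotopic_mass`, `endogenous_or_essential`, and
#'   optionally `hmdb_id`).
#' @param rules Adduct rules: a data.frame like [adductRegistry()] or a
#'   character vector of adduct names. Must be non-empty; gate to the
#'   dataset's polarity before matching (see `polarity`).
#' @param tol Mass tolerance in Da (default 0.025, the published search
#'   tolerance).
#' @param polarity Optional: `"positive"` or `"negative"` restricts `rules`
#'   to that polarity.
#' @return data.frame of hits: `observedMz`, `adduct`, `kegg_id`, `name`,
#'   `theoreticalMz`, `error` (signed, observed - theoretical),
#'   `endogenous_or_essential`.
#' @examples
#' db <- readMetaboliteTable(bundledMetaboliteDb())
#' matchMz(221.97144, db, adductRegistry("positive"))
#' @export
matchMz <- function(observedMz, db, rules, tol = 0.025, polarity = NULL) {
  stopifnot(length(observedMz) == 1L, is.finite(observedMz), tol > 0)
  if (is.character(rules))
    rules <- do.call(rbind, lapply(rules, function(nm) {
      r <- parseAdduct(nm)
      data.frame(name = nm, n = r$n, delta = r$delta, polarity = r$polarity)
    }))
  if (!is.null(polarity)) {
    want <- if (polarity == "positive") 1L else -1L
    rules <- rules[rules$polarity == want, , drop = FALSE]
  }
  if (is.null(rules) || !nrow(rules))
    stop("empty adduct rule set (after polarity gating)")
  if (!nrow(db))
    return(data.frame(observedMz = numeric(), adduct = character(),
                      kegg_id = character(), name = character(),
                      theoreticalMz = numeric(), error = numeric(),
                      endogenous_or_essential = logical()))
  # |db| x |rules| theoretical m/z grid
  theo <- outer(db$monoisotopic_mass, rules$n, `*`) +
    matrix(rules$delta, nrow(db), nrow(rules), byrow = TRUE)
  err <- observedMz - theo
  hit <- which(abs(err) <= tol, arr.ind = TRUE)
  out <- data.frame(
    observedMz = rep(observedMz, nrow(hit)),
    adduct = rules$name[hit[, 2]],
    kegg_id = db$kegg_id[hit[, 1]],
    name = db$name[hit[, 1]],
    theoreticalMz = theo[hit],
    error = err[hit],
    endogenous_or_essential = db$endogenous_or_essential[hit[, 1]],
    stringsAsFactors = FALSE)
  if ("hmdb_id" %in% names(db)) out$hmdb_id <- db$hmdb_id[hit[, 1]]
  out[order(abs(out$error)), , drop = FALSE]
}

#' Filter annotation hits to unique endogenous/essential single hits
#'
#' Applies the published hit-filtering rule: hits whose metabolite lacks a
#' KEGG id or the endogenous/essential flag are dropped; then an observed
#' m/z is kept only if exactly one metabolite remains for it. Several adduct
#' explanations of the same metabolite count as one hit (the one with the
#' smallest absolute mass error is reported); two or more distinct
#' metabolites within tolerance discard the m/z as a multiple hit.
#'
#' @param hits data.frame of hits (possibly for several observed m/z), as
#'   returned by [matchMz()].
#' @return data.frame with one row per surviving observed m/z, with a
#'   `unique` column (always `TRUE` on output).
#' @export
filterAnnotations <- function(hits) {
  empty <- hits[0, , drop = FALSE]
  if (!nrow(hits)) { empty$unique <- logical(); return(empty) }
  ok <- !is.na(hits$kegg_id) & nzchar(hits$kegg_id) &
    hits$endogenous_or_essential %in% TRUE
  hits <- hits[ok, , drop = FALSE]
  if (!nrow(hits)) { empty$unique <- logical(); return(empty) }
  kept <- lapply(split(hits, hits$observedMz), function(g) {
    if (length(unique(g$kegg_id)) != 1L) return(NULL)  # isobaric: discard
    g[which.min(abs(g$error)), , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  if (is.null(out)) { empty$unique <- logical(); return(empty) }
  out$unique <- TRUE
  rownames(out) <- NULL
  out[order(out$observedMz), , drop = FALSE]
}

#' Annotate a differential table with metabolite assignments
#'
#' Joins the significant m/z of a differential table with their filtered
#' metabolite annotations (see [matchMz()] and [filterAnnotations()]),
#' producing a report in the published schema: m/z, adduct, KEGG id,
#' metabolite, cell/plasma ratio, instrument setting, cell type.
#'
#' @param diff Differential table from [differentialTable()].
#' @param db Metabolite table ([readMetaboliteTable()]).
#' @param rules Adduct rules; default the registry gated to the table's
#'   polarity (when the table carries one).
#' @param tol Mass tolerance in Da (default 0.025).
#' @return data.frame with columns `mz`, `adduct`, `kegg_id`, `metabolite`,
#'   `cellPlasmaRatio`, `settingLabel`, `cellType`, `massError`.
#' @export
annotateDiffTable <- function(diff, db, rules = NULL, tol = 0.025) {
  pol <- if ("polarity" %in% names(diff) && nrow(diff))
    diff$polarity[1] else NULL
  if (is.null(rules))
    rules <- if (!is.null(pol)) adductRegistry(pol) else adductRegistry()
  sig <- diff[diff$significant %in% TRUE, , drop = FALSE]
  out <- data.frame(mz = numeric(), adduct = character(),
                    kegg_id = character(), metabolite = character(),
                    cellPlasmaRatio = numeric(),
                    settingLabel = character(), cellType = character(),
                    massError = numeric(), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(sig))) {
    hits <- filterAnnotations(
      matchMz(sig$mz[r], db, rules, tol = tol))
    if (!nrow(hits)) next
    out <- rbind(out, data.frame(
      mz = sig$mz[r], adduct = hits$adduct, kegg_id = hits$kegg_id,
      metabolite = hits$name, cellPlasmaRatio = sig$foldChange[r],
      settingLabel = if ("settingLabel" %in% names(sig))
        sig$settingLabel[r] else NA_character_,
      cellType = sig$cellType[r], massError = hits$error,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
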