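#' @title Elemental-formula and adduct m/z arithmetic
#'
#' @description
#' Monoisotopic mass computation from elemental formulas and adduct-transform
#' arithmetic for singly charged MALDI ions. The adduct grammar covers the
#' forms encountered in blood-smear MSI work: `nM +/- species` with species
#' drawn from H, Na, K, Cl and H2O, e.g. `"M-H"`, `"2M+Na"`, `"M+H-2H2O"`,
#' plus the bare radical cation `"M"` (used for Fe(III) heme).
#'
#' @details
#' The default mass convention uses neutral atomic masses with no
#' electron-mass correction: protonation adds the mass of a hydrogen atom
#' (1.00783 Da), sodiation the mass of a sodium atom, and so on. All ions are
#' treated as singly charged. An optional electron-mass correction
#' (subtracting the electron mass times the ion charge) is available via
#' `electronCorrection = TRUE`; the two conventions differ by about 0.0005 Da,
#' far inside the 0.025 Da annotation tolerance used downstream.
#'
#' @name chemmass
NULL

# Monoisotopic masses of the most abundant isotope (Da), IUPAC/CODATA values.
# Kept as an internal constant and mirrored in inst/extdata/element_masses.csv;
# never fetched at runtime.
.ELEMENT_MASSES <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Fe = 55.9349375,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  Se = 79.9165213,
  Mo = 97.9054082,
  I  = 126.904473
)

.PROTON_MASS   <- 1.00727646688
.ELECTRON_MASS <- 0.00054857990907
.H2O_MASS <- 2 * .ELEMENT_MASSES[["H"]] + .ELEMENT_MASSES[["O"]]

#' Monoisotopic element mass table
#'
#' Returns the fixed table of monoisotopic element masses used throughout the
#' package, together with the proton and electron masses.
#'
#' @return A named numeric vector of monoisotopic masses in Da. The attributes
#'   `proton` and `electron` carry the proton and electron masses.
#' @examples
#' elementMasses()[["Fe"]]
#' @export
elementMasses <- function() {
  m <- .ELEMENT_MASSES
  attr(m, "proton") <- .PROTON_MASS
  attr(m, "electron") <- .ELECTRON_MASS
  m
}

#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula string such as `"C10H16N5O13P3"`
#' into a named count vector.
#'
#' @param formula Character scalar, e.g. `"H2O"`.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C4H9NO5S")
#' @export
parseFormula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula))
    stop("'formula' must be a single non-empty character string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula))
    stop("cannot parse formula '", formula, "'")
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  unknown <- setdiff(sym, names(.ELEMENT_MASSES))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  if (all(out == 0L)) stop("formula '", formula, "' contains no atoms")
  out[out > 0L]
}

#' Monoisotopic mass of a formula
#'
#' @param formula Character formula string (e.g. `"C34H32FeN4O4"`) or a named
#'   count vector as returned by [parseFormula()].
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopicMass("H2O")           # 18.01056
#' monoisotopicMass("C10H16N5O13P3") # ATP, 506.99575
#' @export
monoisotopicMass <- function(formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  if (!length(formula) || is.null(names(formula)))
    stop("'formula' must be a formula string or named count vector")
  unknown <- setdiff(names(formula), names(.ELEMENT_MASSES))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(.ELEMENT_MASSES[names(formula)] * as.numeric(formula))
}

# mass delta (Da) of one adduct species token
.SPECIES_MASS <- function(species) {
  switch(species,
    H   = .ELEMENT_MASSES[["H"]],
    Na  = .ELEMENT_MASSES[["Na"]],
    K   = .ELEMENT_MASSES[["K"]],
    Cl  = .ELEMENT_MASSES[["Cl"]],
    H2O = .H2O_MASS,
    stop("unknown adduct species '", species, "'")
  )
}

# charge sign contributed by gaining one unit of a species
.SPECIES_CHARGE <- c(H = 1L, Na = 1L, K = 1L, Cl = -1L, H2O = 0L)

#' Parse an adduct name
#'
#' Parses an adduct descriptor of the grammar `n?M((+|-)k?species)*` with
#' species in `{H, Na, K, Cl, H2O}` into its multiplier, mass delta and
#' polarity. The spelling `"H20"` (digit zero) is accepted as an alias of
#' `"H2O"`. The bare form `"M"` denotes a singly charged radical/intrinsic
#' cation (polarity +1, zero delta), as used for Fe(III) heme.
#'
#' @param name Adduct string, e.g. `"M-H"`, `"2M+Na"`, `"M+H-2H2O"`.
#' @return A list of class `AdductRule` with elements `name`, `n`
#'   (multiplier of M), `delta` (signed Da), `polarity` (+1 or -1).
#' @examples
#' parseAdduct("2M+Na")
#' parseAdduct("M-H20-H")  # legacy spelling of M-H2O-H
#' @export
parseAdduct <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("'name' must be a single adduct string")
  canonical <- gsub("H20", "H2O", name, fixed = TRUE)
  m <- regexec("^([0-9]*)M((?:[+-][0-9]*(?:H2O|Na|K|Cl|H))*)$", canonical,
               perl = TRUE)
  parts <- regmatches(canonical, m)[[1]]
  if (!length(parts))
    stop("cannot parse adduct '", name, "'; accepted grammar: ",
         "n?M((+|-)k?species)* with species in {H, Na, K, Cl, H2O}")
  n <- if (nzchar(parts[2])) as.integer(parts[2]) else 1L
  if (n < 1L) stop("multiplier in adduct '", name, "' must be >= 1")
  delta <- 0
  charge <- 0L
  tail <- parts[3]
  if (nzchar(tail)) {
    tm <- gregexpr("([+-])([0-9]*)(H2O|Na|K|Cl|H)", tail, perl = TRUE)[[1]]
    toks <- regmatches(tail, list(tm))[[1]]
    for (tok in toks) {
      sign <- if (substr(tok, 1, 1) == "+") 1 else -1
      body <- substring(tok, 2)
      k <- sub("(H2O|Na|K|Cl|H)$", "", body)
      k <- if (nzchar(k)) as.integer(k) else 1L
      species <- sub("^[0-9]*", "", body)
      delta <- delta + sign * k * .SPECIES_MASS(species)
      charge <- charge + as.integer(sign) * k * .SPECIES_CHARGE[[species]]
    }
  }
  polarity <- if (charge > 0L) 1L else if (charge < 0L) -1L else 1L
  structure(list(name = name, n = n, delta = delta, polarity = polarity),
            class = "AdductRule")
}

#' @export
print.AdductRule <- function(x, ...) {
  cat(sprintf("AdductRule '%s': n=%d, delta=%+.5f Da, polarity=%+d\n",
              x$name, x$n, x$delta, x$polarity))
  invisible(x)
}

#' Adduct m/z of a neutral mass
#'
#' Computes the m/z of a singly charged adduct ion `n M +/- species` from the
#' neutral monoisotopic mass.
#'
#' @param neutralMass Neutral monoisotopic mass in Da (positive scalar or
#'   vector).
#' @param rule An `AdductRule` from [parseAdduct()], or an adduct string.
#' @param electronCorrection If `TRUE`, subtract `polarity * electron mass`
#'   so that cation masses lose and anion masses gain one electron. Default
#'   `FALSE` (plain atomic-mass convention).
#' @return m/z in Da.
#' @examples
#' adductMz(monoisotopicMass("C10H16N5O13P3"), "M-H")   # ATP [M-H]-, 505.988
#' adductMz(monoisotopicMass("C10H13N4O8P"), "M+Na")    # IMP [M+Na]+, 371.037
#' @export
adductMz <- function(neutralMass, rule, electronCorrection = FALSE) {
  if (is.character(rule)) rule <- parseAdduct(rule)
  if (any(!is.finite(neutralMass)) || any(neutralMass <= 0))
    stop("'neutralMass' must be positive and finite")
  mz <- rule$n * neutralMass + rule$delta
  if (isTRUE(electronCorrection)) mz <- mz - rule$polarity * .ELECTRON_MASS
  mz
}

#' Invert an adduct transform
#'
#' Recovers the neutral monoisotopic mass from an observed adduct m/z.
#'
#' @inheritParams adductMz
#' @param mz Observed m/z (Da).
#' @return Neutral mass in Da.
#' @export
neutralMass <- function(mz, rule, electronCorrection = FALSE) {
  if (is.character(rule)) rule <- parseAdduct(rule)
  if (isTRUE(electronCorrection)) mz <- mz + rule$polarity * .ELECTRON_MASS
  (mz - rule$delta) / rule$n
}

#' Adduct registry
#'
#' The registry of adduct rules observed in blood-smear MSI annotation work,
#' split by ionization polarity. Negative mode: M-H, 2M-H, M-H2O-H, M+Cl.
#' Positive mode: M, M+H, M+Na, M+K, 2M+H, 2M+Na, 2M+K, M+H-H2O, M+H-2H2O,
#' 2M+H-H2O.
#'
#' @param polarity `"positive"`, `"negative"` or `"both"` (default).
#' @return A data.frame with columns `name`, `n`, `delta`, `polarity`.
#' @examples
#' adductRegistry("negative")
#' @export
adductRegistry <- function(polarity = c("both", "positive", "negative")) {
  polarity <- match.arg(polarity)
  names <- c("M-H", "2M-H", "M-H2O-H", "M+Cl",
             "M", "M+H", "M+Na", "M+K", "2M+H", "2M+Na", "2M+K",
             "M+H-H2O", "M+H-2H2O", "2M+H-H2O")
  rules <- lapply(names, parseAdduct)
  df <- data.frame(
    name = names,
    n = vapply(rules, `[[`, integer(1), "n"),
    delta = vapply(rules, `[[`, numeric(1), "delta"),
    polarity = vapply(rules, `[[`, integer(1), "polarity"),
    stringsAsFactors = FALSE
  )
  if (polarity == "positive") df <- df[df$polarity > 0L, ]
  if (polarity == "negative") df <- df[df$polarity < 0L, ]
  rownames(df) <- NULL
  df
}
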