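test_that("monoisotopic masses match independent hand sums", {
  expect_equal(monoisotopicMass("H2O"),
               2 * ORACLE_MASS["H"] + ORACLE_MASS["O"],
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(monoisotopicMass("H2O"), 18.01056, tolerance = 1e-5)
  # ATP
  atp <- 10 * ORACLE_MASS["C"] + 16 * ORACLE_MASS["H"] +
    5 * ORACLE_MASS["N"] + 13 * ORACLE_MASS["O"] + 3 * ORACLE_MASS["P"]
  expect_equal(monoisotopicMass("C10H16N5O13P3"), unname(atp),
               tolerance = 1e-9)
  expect_equal(monoisotopicMass("C10H16N5O13P3"), 506.99575,
               tolerance = 1e-5)
  # repeated element symbols accumulate
  expect_equal(monoisotopicMass("CH3COOH"), monoisotopicMass("C2H4O2"))
})

test_that("formula parsing rejects unknown symbols and empty formulas", {
  expect_error(parseFormula("X9"), "unknown element")
  expect_error(monoisotopicMass("C3Zz2"), "unknown element")
  expect_error(parseFormula(""), "non-empty")
  expect_error(parseFormula("C0"), "no atoms")
  expect_equal(parseFormula("C4H9NO5S"),
               c(C = 4L, H = 9L, N = 1L, O = 5L, S = 1L))
})

test_that("element mass table is physically consistent", {
  m <- elementMasses()
  expect_true(all(m > 0))
  expect_lt(abs(m[["H"]] - attr(m, "proton") - attr(m, "electron")), 1e-6)
})

test_that("adduct grammar parses to (n, delta, polarity) deterministically", {
  r <- parseAdduct("M-H")
  expect_equal(r$n, 1L)
  expect_equal(r$delta, -1.00783, tolerance = 1e-5)
  expect_equal(r$polarity, -1L)

  r <- parseAdduct("2M+Na")
  expect_equal(r$n, 2L)
  expect_equal(r$delta, 22.98977, tolerance = 1e-5)
  expect_equal(r$polarity, 1L)

  r <- parseAdduct("M")
  expect_equal(list(r$n, r$delta, r$polarity), list(1L, 0, 1L))

  # chloride attachment is a negative-mode adduct
  expect_equal(parseAdduct("M+Cl")$polarity, -1L)
  # water losses carry no charge
  r <- parseAdduct("M+H-2H2O")
  expect_equal(r$polarity, 1L)
  expect_equal(r$delta, ORACLE_MASS[["H"]] -
                 2 * (2 * ORACLE_MASS[["H"]] + ORACLE_MASS[["O"]]),
               tolerance = 1e-9)
})

test_that("the published digit-zero spelling H20 aliases H2O", {
  a <- parseAdduct("M-H20-H")
  b <- parseAdduct("M-H2O-H")
  expect_equal(a$delta, b$delta)
  expect_equal(a$polarity, b$polarity)
})

test_that("unparseable adducts name the accepted grammar", {
  expect_error(parseAdduct("M+Fe"), "grammar")
  expect_error(parseAdduct("MH"), "grammar")
  expect_error(parseAdduct(""), "adduct")
})

test_that("adduct m/z reproduces the printed marker values at 3 decimals", {
  expect_equal(round(adductMz(506.99575, "M-H"), 3), 505.988)
  expect_equal(round(adductMz(348.04711, "M+Na"), 3), 371.037)
  expect_equal(round(adductMz(616.17729, "M"), 3), 616.177)
})

test_that("2M rules equal M rules applied to the doubled mass", {
  masses <- c(89.1, 183.020143, 371.3, 616.177)
  for (sp in c("+H", "+Na", "+K", "-H")) {
    r2 <- parseAdduct(paste0("2M", sp))
    r1 <- parseAdduct(paste0("M", sp))
    expect_equal(adductMz(masses, r2), adductMz(2 * masses, r1))
  }
})

test_that("neutral mass is recovered by the inverse transform", {
  reg <- adductRegistry()
  masses <- c(151.9779, 304.090665, 825.705)
  for (i in seq_len(nrow(reg))) {
    mz <- adductMz(masses, reg[i, ])
    expect_equal(neutralMass(mz, reg[i, ]), masses, tolerance = 1e-9)
  }
})

test_that("formula + adduct chains match independent oracle sums", {
  oracleMass <- function(counts) sum(ORACLE_MASS[names(counts)] * counts)
  cases <- list(
    list(c(C = 4, H = 9, N = 1, O = 5, S = 1), "C4H9NO5S", "M+K",
         delta = ORACLE_MASS[["K"]], n = 1),
    list(c(C = 5, H = 10, N = 1, O = 7, P = 1), "C5H10NO7P", "M+K",
         delta = ORACLE_MASS[["K"]], n = 1),
    list(c(C = 10, H = 7, N = 1, O = 4), "C10H7NO4", "2M-H",
         delta = -ORACLE_MASS[["H"]], n = 2),
    list(c(C = 34, H = 32, Fe = 1, N = 4, O = 4), "C34H32FeN4O4", "M", 0, 1),
    list(c(C = 10, H = 14, N = 4, O = 11, P = 2), "C10H14N4O11P2", "M-H2O-H",
         delta = -(3 * ORACLE_MASS[["H"]] + ORACLE_MASS[["O"]]), n = 1))
  for (cs in cases) {
    expected <- cs[[5]] * oracleMass(cs[[1]]) + cs[[4]]
    expect_equal(adductMz(monoisotopicMass(cs[[2]]), cs[[3]]),
                 unname(expected), tolerance = 1e-4)
  }
})

test_that("electron-mass correction shifts ions by one electron mass", {
  em <- attr(elementMasses(), "electron")
  m <- 506.99575
  expect_equal(adductMz(m, "M-H", electronCorrection = TRUE),
               adductMz(m, "M-H") + em)
  expect_equal(adductMz(m, "M+Na", electronCorrection = TRUE),
               adductMz(m, "M+Na") - em)
  # the two conventions never differ by more than ~0.0011 Da
  expect_lt(abs(adductMz(m, "M+Na", electronCorrection = TRUE) -
                  adductMz(m, "M+Na")), 0.0011)
})

test_that("the adduct registry gates by polarity and covers both modes", {
  reg <- adductRegistry()
  expect_setequal(adductRegistry("negative")$name,
                  c("M-H", "2M-H", "M-H2O-H", "M+Cl"))
  expect_true(all(c("M", "M+H", "M+Na", "M+K", "2M+H", "2M+Na", "2M+K",
                    "M+H-H2O", "M+H-2H2O", "2M+H-H2O") %in%
                    adductRegistry("positive")$name))
  expect_equal(nrow(adductRegistry("positive")) +
                 nrow(adductRegistry("negative")), nrow(reg))
})
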