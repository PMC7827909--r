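test_that("matching finds the homocysteic acid M+K assignment", {
  db <- readMetaboliteTable(bundledMetaboliteDb())
  hits <- matchMz(221.97144, db, adductRegistry("positive"))
  expect_true("C16511" %in% hits$kegg_id)
  h <- hits[hits$kegg_id == "C16511" & hits$adduct == "M+K", ]
  expect_lte(abs(h$error), 0.025)
  expect_equal(abs(h$error), 0.01241, tolerance = 1e-4)
  # hits come back sorted by absolute error
  expect_true(!is.unsorted(abs(hits$error)))
})

test_that("matching handles empty inputs and tight tolerances", {
  db <- readMetaboliteTable(bundledMetaboliteDb())
  expect_equal(nrow(matchMz(300, db[0, ], adductRegistry("positive"))), 0L)
  expect_equal(nrow(matchMz(221.9, db, adductRegistry("positive"),
                            tol = 1e-6)), 0L)
  expect_error(matchMz(300, db, adductRegistry("positive")[0, ]),
               "empty adduct rule set")
  expect_error(matchMz(300, db, adductRegistry(), polarity = "positive",
                       tol = 0), "tol")
})

test_that("matching agrees exactly with a brute-force scan", {
  bruteForce <- function(obs, db, rules, tol) {
    out <- NULL
    for (i in seq_len(nrow(db))) for (j in seq_len(nrow(rules))) {
      theo <- rules$n[j] * db$monoisotopic_mass[i] + rules$delta[j]
      if (abs(obs - theo) <= tol)
        out <- rbind(out, data.frame(kegg_id = db$kegg_id[i],
                                     adduct = rules$name[j], theo = theo))
    }
    out
  }
  set.seed(13)
  rules <- adductRegistry()
  for (rep in 1:20) {
    db <- data.frame(
      kegg_id = sprintf("C%05d", seq_len(sample(5:100, 1))),
      name = "x", endogenous_or_essential = TRUE)
    db$monoisotopic_mass <- runif(nrow(db), 100, 900)
    obs <- runif(1, 100, 950)
    tol <- runif(1, 0.001, 0.5)
    got <- matchMz(obs, db, rules, tol = tol)
    want <- bruteForce(obs, db, rules, tol)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      key <- function(d, ad) paste(d$kegg_id, ad)
      expect_setequal(key(got, got$adduct), key(want, want$adduct))
      expect_true(all(abs(got$error) <= tol))
    }
  }
})

test_that("widening the tolerance never removes a hit", {
  db <- readMetaboliteTable(bundledMetaboliteDb())
  rules <- adductRegistry("positive")
  set.seed(14)
  for (obs in runif(10, 200, 900)) {
    narrow <- matchMz(obs, db, rules, tol = 0.01)
    wide <- matchMz(obs, db, rules, tol = 0.05)
    key <- paste(narrow$kegg_id, narrow$adduct)
    expect_true(all(key %in% paste(wide$kegg_id, wide$adduct)))
  }
})

test_that("hit filtering keeps unique endogenous KEGG metabolites only", {
  mkhits <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(observedMz = r[[1]], adduct = r[[2]], kegg_id = r[[3]],
                 name = r[[4]], theoreticalMz = r[[1]] - r[[5]],
                 error = r[[5]],
                 endogenous_or_essential = r[[6]],
                 stringsAsFactors = FALSE)))
  }
  # two distinct metabolites within tolerance: m/z discarded as isobaric
  h <- mkhits(list(300.1, "M+H", "C1", "a", 0.002, TRUE),
              list(300.1, "M+Na", "C2", "b", 0.004, TRUE))
  expect_equal(nrow(filterAnnotations(h)), 0L)
  # one metabolite via two adducts: kept once, smaller |error| reported
  h <- mkhits(list(300.1, "M+H", "C1", "a", 0.01, TRUE),
              list(300.1, "2M+Na", "C1", "a", -0.003, TRUE))
  kept <- filterAnnotations(h)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$adduct, "2M+Na")
  expect_true(kept$unique)
  # a single hit without KEGG id is discarded
  h <- mkhits(list(300.1, "M+H", "", "a", 0.002, TRUE))
  expect_equal(nrow(filterAnnotations(h)), 0L)
  # non-endogenous single hits are discarded
  h <- mkhits(list(300.1, "M+H", "C1", "a", 0.002, FALSE))
  expect_equal(nrow(filterAnnotations(h)), 0L)
  # independent m/z are filtered independently
  h <- mkhits(list(300.1, "M+H", "C1", "a", 0.002, TRUE),
              list(300.1, "M+H", "C2", "b", 0.004, TRUE),
              list(455.2, "M+K", "C3", "c", -0.001, TRUE))
  kept <- filterAnnotations(h)
  expect_equal(kept$kegg_id, "C3")
})

test_that("published differential m/z annotate to their printed metabolites", {
  db <- readMetaboliteTable(bundledMetaboliteDb())
  dmz <- utils::read.delim(bundledDiffMzTable())
  # rows whose curated formula confirms the printed assignment at 0.025 Da
  for (r in which(dmz$validates)) {
    pol <- if (grepl("\\+$", dmz$setting[r])) "positive" else "negative"
    kept <- filterAnnotations(matchMz(dmz$mz[r], db, adductRegistry(pol)))
    expect_equal(kept$kegg_id, dmz$kegg_id[r])
    # fixture keeps the published digit-zero spelling; compare canonicalized
    expect_equal(kept$adduct, gsub("H20", "H2O", dmz$adduct[r], fixed = TRUE),
                 label = sprintf("adduct for m/z %.5f", dmz$mz[r]))
  }
  expect_gte(sum(dmz$validates), 46L)
})

test_that("the heme cation annotates via the bare-M rule", {
  # printed as M+H, but the m/z matches the intact Fe(III) cation [M]+
  db <- readMetaboliteTable(bundledMetaboliteDb())
  heme <- db[db$kegg_id == "C00032", ]
  viaMH <- matchMz(616.17073, heme, "M+H")
  expect_equal(nrow(viaMH), 0L)
  viaM <- filterAnnotations(matchMz(616.17073, heme, adductRegistry("positive")))
  expect_equal(viaM$adduct, "M")
  expect_lte(abs(viaM$error), 0.025)
})

test_that("annotated differential reports carry the published schema", {
  dt <- data.frame(mz = c(221.97144, 300.5), t = c(5, 1), p = c(0.001, 0.4),
                   foldChange = c(1.6, 1.1), infiniteFold = FALSE,
                   significant = c(TRUE, FALSE), cellType = "RBC",
                   settingLabel = "D0", polarity = "positive")
  db <- readMetaboliteTable(bundledMetaboliteDb())
  rep <- annotateDiffTable(dt, db)
  expect_equal(names(rep), c("mz", "adduct", "kegg_id", "metabolite",
                             "cellPlasmaRatio", "settingLabel", "cellType",
                             "massError"))
  expect_equal(rep$kegg_id, "C16511")
  expect_equal(rep$cellPlasmaRatio, 1.6)
  # non-significant rows never annotate; empty tables give empty reports
  expect_equal(nrow(annotateDiffTable(dt[dt$p > 0.1, ], db)), 0L)
})
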