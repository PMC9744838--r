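test_that("tryptic digestion applies the after-K/R-not-before-P rule", {
  d <- digestTryptic("AKRPGK", maxMissed = 1, minLen = 1, maxLen = 50)
  expect_setequal(d$peptide, c("AK", "RPGK", "AKRPGK"))
  expect_equal(d[d$peptide == "RPGK", c("start", "end")],
               data.frame(start = 3L, end = 6L, row.names = 3L))
  expect_equal(d$missed_cleavages[d$peptide == "AKRPGK"], 1)

  nocut <- digestTryptic("GGG", 1, 1, 50)
  expect_equal(nocut$peptide, "GGG")
  expect_equal(c(nocut$start, nocut$end), c(1, 3))

  expect_error(digestTryptic("ACXDE"), "position 3")
})

test_that("digestion agrees with the brute-force substring oracle", {
  set.seed(42)
  for (i in 1:25) {
    s <- randomSeq(sample(10:80, 1))
    for (mm in 0:2) {
      got <- digestTryptic(s, maxMissed = mm, minLen = 1, maxLen = Inf)
      want <- oracleDigest(s, maxMissed = mm)
      expect_equal(got, want, info = paste("seq", i, "missed", mm))
    }
  }
})

test_that("maxMissed=0 digest is the zero-missed subset of maxMissed=1", {
  set.seed(7)
  for (i in 1:10) {
    s <- randomSeq(60)
    d0 <- digestTryptic(s, maxMissed = 0)
    d1 <- digestTryptic(s, maxMissed = 1)
    expect_equal(d0, d1[d1$missed_cleavages == 0, ],
                 ignore_attr = "row.names")
  }
})

test_that("fully cleaved products are digestion fixed points", {
  set.seed(11)
  s <- randomSeq(120)
  for (p in digestTryptic(s, maxMissed = 0)$peptide) {
    redo <- digestTryptic(p, maxMissed = 0)
    expect_equal(redo$peptide, p)
  }
})

test_that("peptide masses reconstruct the parent mass", {
  set.seed(3)
  for (i in 1:10) {
    s <- randomSeq(sample(30:150, 1))
    peps <- digestTryptic(s, maxMissed = 0)$peptide
    total <- sum(vapply(peps, monoisotopicMass, numeric(1)))
    expect_equal(total - (length(peps) - 1) * 18.010565,
                 monoisotopicMass(s), tolerance = 1e-6 / 1000)
  }
})

test_that("monoisotopic masses match the summation oracle", {
  expect_equal(monoisotopicMass("G"), 75.03203, tolerance = 1e-7)
  expect_equal(monoisotopicMass("SELVNWYLK"), 1150.6022, tolerance = 1e-4)
  expect_equal(monoisotopicMass("GDINVCIVGDPSTAK", "carbamidomethyl"),
               1544.7504, tolerance = 1e-4)
  set.seed(5)
  for (i in 1:20) {
    s <- randomSeq(sample(5:40, 1))
    expect_equal(monoisotopicMass(s), oracleMass(s), tolerance = 1e-9)
  }
})

test_that("modifications apply per rule and reject mismatched targets", {
  base <- monoisotopicMass("ACMCA")
  expect_equal(monoisotopicMass("ACMCA", "carbamidomethyl"),
               base + 2 * 57.02146, tolerance = 1e-7)
  expect_equal(monoisotopicMass("ACMCA", "pyridylethyl"),
               base + 2 * 105.05785, tolerance = 1e-7)
  expect_equal(
    monoisotopicMass("ACMCA",
                     variableMods = list(list(position = 3,
                                              mod = "oxidation_m"))),
    base + 15.99491, tolerance = 1e-7)
  expect_error(
    monoisotopicMass("ACMCA",
                     variableMods = list(list(position = 1,
                                              mod = "oxidation_m"))),
    "position 1")
})

test_that("m/z follows (M + z*proton)/z and matches observed MCM6 values", {
  expect_equal(round(mzFromMass(1150.6022, 2), 2), 576.31)
  expect_equal(round(mzFromMass(1544.7504, 2), 2), 773.38)
  expect_equal(round(mzFromMass(1628.8888, 3), 2), 543.97)
  expect_error(mzFromMass(1000, 0), "charge")
  expect_error(mzFromMass(-5, 1), "mass")
})

test_that("ppm error is signed, symmetric, and NA-propagating", {
  expect_equal(ppmError(500.0000, 500.0000), 0)
  expect_equal(ppmError(500.0025, 500.0000), 5, tolerance = 1e-9)
  expect_equal(ppmError(499.9975, 500.0000), -5, tolerance = 1e-9)
  expect_true(is.na(ppmError(NA_real_, 500)))
  expect_error(ppmError(500, -1), "positive")
})

test_that("peptide uniqueness is exact cross-protein comparison", {
  disjoint <- list(A = c("PEPA", "PEPB"), B = c("PEPC", "PEPD"))
  expect_true(all(uniquePeptideMap(disjoint)$status == "unique"))

  twin <- list(A = c("PEPA", "PEPB"), B = c("PEPA", "PEPB"))
  expect_true(all(uniquePeptideMap(twin)$status == "shared"))

  toy <- list(P1 = c("AAK", "CCK", "SHAREDK"),
              P2 = c("DDK", "SHAREDK"),
              P3 = c("EEK", "FFK"))
  m <- uniquePeptideMap(toy)
  expect_equal(m$status[m$peptide == "SHAREDK"], "shared")
  expect_true(all(m$status[m$peptide != "SHAREDK"] == "unique"))
  expect_equal(m$accession[m$peptide == "DDK"], "P2")
})
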