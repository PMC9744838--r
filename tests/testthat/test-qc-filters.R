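test_that("minimum-unique-peptide filter retains >= k and logs a trace", {
  rep <- toyReport(c("A", "B", "C"), npep = c(1, 2, 3))
  out <- filterMinUniquePeptides(rep, 2)
  expect_setequal(accessions(out$report), c("B", "C"))
  expect_equal(out$trace$n_in, 3)
  expect_equal(out$trace$n_out, 2)
  expect_equal(out$trace$removed, "A")

  ident <- filterMinUniquePeptides(rep, 1)
  expect_equal(nrow(entries(ident$report)), 3)

  emptyRep <- ProteinReport(toyEntries(character()), "empty")
  e <- filterMinUniquePeptides(emptyRep, 2)
  expect_equal(c(e$trace$n_in, e$trace$n_out), c(0, 0))
})

test_that("the peptide filter is monotone in k", {
  set.seed(9)
  rep <- toyReport(paste0("P", 1:40), npep = sample(0:6, 40, TRUE))
  prev <- accessions(filterMinUniquePeptides(rep, 1)$report)
  for (k in 2:6) {
    cur <- accessions(filterMinUniquePeptides(rep, k)$report)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("contaminant screening matches accession or gene and reports", {
  rep <- toyReport(c("P1", "P2", "P3"), gene = c("KRT5", "GAPDH", ""))
  out <- screenContaminants(rep, c("KRT5", "KRT19"))
  expect_setequal(accessions(out$report), c("P2", "P3"))
  expect_equal(out$found, "KRT5")

  clean <- screenContaminants(toyReport(c("X1", "X2")), c("KRT5"))
  expect_equal(nrow(entries(clean$report)), 2)
  expect_length(clean$found, 0)

  seven <- toyReport(paste0("Q", 1:7),
                     gene = c("KRT19", "A", "B", "KRT7", "C", "D", "E"))
  s7 <- screenContaminants(seven, c("KRT19", "KRT7"))
  expect_equal(nrow(entries(s7$report)), 5)
  expect_length(s7$found, 2)

  # match through a mapping table when the report lacks gene symbols
  viaMap <- screenContaminants(toyReport("Z9"), "KRT5",
                               mapping = c(Z9 = "KRT5"))
  expect_equal(nrow(entries(viaMap$report)), 0)

  # report-only mode flags but retains
  keep <- screenContaminants(rep, "KRT5", action = "report")
  expect_equal(nrow(entries(keep$report)), 3)
  expect_equal(keep$found, "KRT5")
})

test_that("filter chain trace reconstructs which rule removed what", {
  rep <- toyReport(c("A", "B", "C", "D"), npep = c(1, 5, 5, 5),
                   gene = c("", "KRT5", "", ""))
  s1 <- screenContaminants(rep, "KRT5")
  s2 <- filterMinUniquePeptides(s1$report, 2)
  trace <- rbind(s1$trace, s2$trace)
  expect_equal(trace$n_out[1], trace$n_in[2])  # counts compose
  expect_equal(trace$removed, c("B", "A"))
  expect_setequal(accessions(s2$report), c("C", "D"))
})

test_that("subset annotation flags mapped genes and counts unmapped", {
  rep <- toyReport(paste0("P", 1:4), gene = c("MCM6", "MCM3", "XYZ", ""))
  allIn <- annotateSubset(rep, c("MCM6", "MCM3", "XYZ"), "skin")
  expect_equal(allIn$nFlagged, 3)
  expect_equal(allIn$unmapped, "P4")

  noneIn <- annotateSubset(rep, character(), "skin")
  expect_equal(noneIn$nFlagged, 0)

  ten <- toyReport(paste0("P", 1:10),
                   gene = c(paste0("G", 1:7), "S1", "S2", "S3"))
  r <- annotateSubset(ten, c("S1", "S2", "S3", "S4"), "sub")
  expect_equal(r$nFlagged, 3)
  expect_true(all(entries(r$report)$in_sub[8:10]))
})

test_that("housekeeping panel reports per-sample NSAF with missing flags", {
  n1 <- computeNSAF(c(A1 = 10, B1 = 5), c(A1 = 100, B1 = 100))
  n2 <- computeNSAF(c(A1 = 12), c(A1 = 100))
  mapping <- c(A1 = "GAPDH", B1 = "PGK1")
  tab <- housekeepingPanel(list(ctl = n1, trt = n2),
                           c("GAPDH", "PGK1"), mapping)
  expect_equal(nrow(tab), 4)
  expect_equal(sum(tab$missing), 1)
  expect_true(tab$missing[tab$gene == "PGK1" & tab$sample == "trt"])
  expect_false(any(is.na(tab$nsaf[!tab$missing])))
})

test_that("housekeeping NSAF stays stable between synthetic conditions", {
  p <- simParams(seed = 19, nProteins = 400,
                 depths = c(deep = 30000, shallow = 8000))
  prot <- simulateProteome(p)
  lens <- setNames(nchar(prot@sequences), names(prot@sequences))
  ctl <- sumReportCounts(lapply(1:3, function(i)
    simulateCounts(prot, "control", "deep", i)))
  trt <- sumReportCounts(lapply(1:3, function(i)
    simulateCounts(prot, "treated", "deep", i)))
  tab <- housekeepingPanel(
    list(control = computeNSAF(ctl, lens), treated = computeNSAF(trt, lens)),
    c("GAPDH", "HPRT", "PGK1", "TBB5"), prot@genes)
  wide <- reshape(tab[, c("gene", "sample", "nsaf")], idvar = "gene",
                  timevar = "sample", direction = "wide")
  ratio <- wide$nsaf.treated / wide$nsaf.control
  expect_true(all(ratio > 0.5 & ratio < 2))
})
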