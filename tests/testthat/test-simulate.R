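# Generator tests run at a reduced problem size where only plumbing is
# checked; study-scale behavior (recovery, null calibration) is exercised
# in the acceptance suite at the default parameters.
.smallParams <- function(seed = 13)
  simParams(seed = seed, nProteins = 250,
            depths = c(deep = 15000, shallow = 4000))

test_that("identical parameters give identical simulations", {
  p <- .smallParams()
  a <- simulateProteome(p)
  b <- simulateProteome(p)
  expect_identical(a@sequences, b@sequences)
  expect_identical(a@abundance, b@abundance)
  expect_identical(geneSets(a@geneSets), geneSets(b@geneSets))
  r1 <- simulateCounts(a, "treated", "deep", 2)
  r2 <- simulateCounts(b, "treated", "deep", 2)
  expect_identical(entries(r1), entries(r2))
})

test_that("per-repeat spectra are conserved at the configured depth", {
  p <- .smallParams()
  prot <- simulateProteome(p)
  deep <- simulateCounts(prot, "control", "deep", 1)
  expect_equal(sum(entries(deep)$spectral_count), 15000)
  shallow <- simulateCounts(prot, "control", "shallow", 1)
  expect_equal(sum(entries(shallow)$spectral_count), 4000)
})

test_that("simulated proteins are identifiable by unique tryptic peptides", {
  prot <- simulateProteome(.smallParams())
  cellular <- setdiff(names(prot@sequences), prot@contaminants)
  frac <- mean(vapply(prot@peptides[cellular],
                      function(d) sum(d$unique) >= 2, logical(1)))
  expect_gte(frac, 0.95)
})

test_that("spiked genes sit in the innermost gene-set fixture", {
  prot <- simulateProteome(.smallParams())
  sets <- geneSets(prot@geneSets)
  inner <- sets[["GO:0000727_BIR_pathway"]]
  up <- prot@deSpec$gene[prot@deSpec$fold > 1]
  expect_true(all(up %in% inner))
  # nesting: disease > proliferation > skin cancer > pathway
  expect_true(all(inner %in% sets[["COSMIC:skin_cancer"]]))
  expect_true(all(sets[["COSMIC:skin_cancer"]] %in%
                  sets[["DOID:14566_proliferation"]]))
  expect_true(all(sets[["DOID:14566_proliferation"]] %in%
                  sets[["DOID:4_disease"]]))
})

test_that("the shallow protocol detects fewer proteins than the deep", {
  prot <- simulateProteome(.smallParams())
  nDeep <- nrow(entries(simulateCounts(prot, "control", "deep", 1)))
  nShallow <- nrow(entries(simulateCounts(prot, "control", "shallow", 1)))
  expect_lt(nShallow, nDeep)
})

test_that("an unspiked simulation has treated/control NSAF ratios near 1", {
  p <- simParams(seed = 23, nProteins = 250,
                 depths = c(deep = 15000, shallow = 4000),
                 deSpec = data.frame(gene = character(),
                                     fold = numeric()))
  prot <- simulateProteome(p)
  lens <- setNames(nchar(prot@sequences), names(prot@sequences))
  ctl <- sumReportCounts(lapply(1:3, function(i)
    simulateCounts(prot, "control", "deep", i)))
  trt <- sumReportCounts(lapply(1:3, function(i)
    simulateCounts(prot, "treated", "deep", i)))
  fc <- foldChanges(computeNSAF(ctl, lens), computeNSAF(trt, lens))
  expect_equal(median(fc$fc), 1, tolerance = 0.1)
})

test_that("a seeded run recovers the spiked fold changes", {
  prot <- simulateProteome(.smallParams(seed = 31))
  lens <- setNames(nchar(prot@sequences), names(prot@sequences))
  ctl <- sumReportCounts(lapply(1:3, function(i)
    simulateCounts(prot, "control", "deep", i)))
  trt <- sumReportCounts(lapply(1:3, function(i)
    simulateCounts(prot, "treated", "deep", i)))
  fc <- foldChanges(computeNSAF(ctl, lens), computeNSAF(trt, lens),
                    genes = prot@genes)
  eight <- fc$fc[fc$gene == "MCM6"]
  expect_true(eight > 5 && eight < 12)
  expect_true(all(fc$direction[fc$gene %in% c("MCM3", "MCM7")] == "up"))
})

test_that("simulateAll writes every fixture byte-identically per seed", {
  p <- .smallParams(seed = 41)
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2")
  m1 <- simulateAll(p, d1)$manifest
  m2 <- simulateAll(p, d2)$manifest
  expect_identical(m1, m2)
  expect_true(all(c("proteome.fasta", "mapping.tsv", "contaminants.txt",
                    "gene_sets.gmt", "qpcr.tsv", "ground_truth.tsv") %in%
                  m1$file))
  # the fixtures are readable with the package's own readers
  seqs <- readFastaSequences(file.path(d1, "proteome.fasta"))
  expect_equal(length(seqs), 255)  # 250 cellular + 5 contaminants
  gsc <- readGMT(file.path(d1, "gene_sets.gmt"))
  expect_gte(length(geneSets(gsc)), 4)
  rep <- readProteinReport(file.path(d1, "report_P1_control_r1.tsv"))
  expect_gt(nrow(entries(rep)), 100)
})
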