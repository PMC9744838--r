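## Ground-truthed synthetic data generator. Emulates the study design the
## pipeline analyzes: 2 sample-preparation protocols (deep / shallow
## detection) x 2 exposure conditions x technical repeats, log-normal
## protein abundances sampled multinomially into spectral counts at a fixed
## per-repeat depth, a spiked differential set (one 8x and two 4x up, a
## 2x-down trio), a stable housekeeping quartet, keratin-like contaminants,
## nested gene-set fixtures, and qPCR Ct plates.

#' SimulationParams: full generative specification
#'
#' @slot seed integer RNG seed; identical params give byte-identical output.
#' @slot nProteins number of cellular proteins (default 1000).
#' @slot lengthRange log-uniform protein length range in aa.
#' @slot abundanceMeanlog,abundanceSdlog log-normal relative-abundance
#'   parameters (defaults 0 and 1.2).
#' @slot depths named total validated spectra per repeat: deep protocol
#'   60000, shallow 15000.
#' @slot membraneFraction fraction of proteins in the "membrane-like"
#'   stratum the shallow protocol under-samples.
#' @slot shallowMembraneBias weight multiplier for that stratum under the
#'   shallow protocol (default 0.3).
#' @slot deSpec data.frame (gene, fold): true treated/control NSAF-scale
#'   fold changes for the spiked proteins.
#' @slot housekeeping gene symbols of the stable quartet (fold 1).
#' @slot contaminants keratin-like contaminant gene symbols.
#' @slot repeats named integer vector of technical repeats per dataset.
#' @slot qpcr list: target, groupFolds (named, control first), references,
#'   baselineCt, refCt, noiseSd, nBio, nTech.
#' @export
setClass("SimulationParams",
  representation(
    seed = "numeric", nProteins = "numeric", lengthRange = "numeric",
    abundanceMeanlog = "numeric", abundanceSdlog = "numeric",
    depths = "numeric", membraneFraction = "numeric",
    shallowMembraneBias = "numeric", deSpec = "data.frame",
    housekeeping = "character", contaminants = "character",
    repeats = "numeric", qpcr = "list"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (object@nProteins < 10) msg <- c(msg, "nProteins must be >= 10")
  if (any(object@deSpec$fold <= 0))
    msg <- c(msg, "fold changes must be > 0")
  if (any(object@depths <= 0) || any(object@repeats < 2))
    msg <- c(msg, "depths must be positive and repeats >= 2")
  if (!all(c("deep", "shallow") %in% names(object@depths)))
    msg <- c(msg, "depths must name 'deep' and 'shallow'")
  if (object@membraneFraction < 0 || object@membraneFraction > 1)
    msg <- c(msg, "membraneFraction must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' Defaults mirror the study design: four datasets (deep protocol, 3+3
#' repeats; shallow protocol, 4+5 repeats), per-repeat depths 60000 / 15000
#' spectra, log-normal(0, 1.2) abundances, an MCM6-like 8x and MCM3/MCM7-
#' like 4x up-regulated spike plus a 2x-down trio, the GAPDH/HPRT/PGK1/TBB5
#' housekeeping quartet, five keratin contaminants, and qPCR plates with
#' true folds 2.8 and 6.1 at Ct noise SD 0.15.
#'
#' @param seed RNG seed.
#' @param nProteins number of cellular proteins.
#' @param depths named c(deep=, shallow=) per-repeat spectra.
#' @param deSpec data.frame(gene, fold) of spiked fold changes.
#' @param repeats named repeats per dataset.
#' @param qpcrNoiseSd Ct technical noise SD.
#' @return a \linkS4class{SimulationParams}.
#' @export
simParams <- function(seed = 1L, nProteins = 1000L,
                      depths = c(deep = 60000, shallow = 15000),
                      deSpec = data.frame(
                        gene = c("MCM6", "MCM3", "MCM7",
                                 "DSC3", "DSP", "PPL"),
                        fold = c(8, 4, 4, 0.5, 0.5, 0.5),
                        stringsAsFactors = FALSE),
                      repeats = c(P1_control = 3, P1_sds = 3,
                                  P2_control = 4, P2_sds = 5),
                      qpcrNoiseSd = 0.15) {
  new("SimulationParams",
      seed = as.numeric(seed), nProteins = as.numeric(nProteins),
      lengthRange = c(60, 3000),
      abundanceMeanlog = 0, abundanceSdlog = 1.2,
      depths = depths, membraneFraction = 0.2,
      shallowMembraneBias = 0.3, deSpec = deSpec,
      housekeeping = c("GAPDH", "HPRT", "PGK1", "TBB5"),
      contaminants = c("KRT19", "KRT7", "KRT16", "KRT5", "KRT15"),
      repeats = repeats,
      qpcr = list(target = "MCM6",
                  groupFolds = c(control = 1, dose1 = 2.8, dose2 = 6.1),
                  references = c("GAPDH", "ACTB"),
                  baselineCt = 24, refCt = 18,
                  noiseSd = qpcrNoiseSd, nBio = 2, nTech = 3))
}

#' SimulatedProteome: a generated proteome with recorded ground truth
#'
#' @slot sequences named character, accession -> sequence.
#' @slot genes named character, accession -> gene symbol.
#' @slot abundance named numeric relative weights (control condition).
#' @slot membrane accessions of the membrane-like stratum.
#' @slot contaminants contaminant accessions.
#' @slot peptides per-accession data.frame of detectable tryptic peptides
#'   (7-30 aa, no missed cleavage) with positions and a proteome-uniqueness
#'   flag.
#' @slot geneSets nested synthetic \linkS4class{GeneSetCollection}.
#' @slot deSpec data.frame accession/gene/fold ground truth.
#' @slot params the generating \linkS4class{SimulationParams}.
#' @export
setClass("SimulatedProteome",
  representation(
    sequences = "character", genes = "character", abundance = "numeric",
    membrane = "character", contaminants = "character",
    peptides = "list", geneSets = "GeneSetCollection",
    deSpec = "data.frame", params = "SimulationParams"
  )
)

setMethod("show", "SimulatedProteome", function(object) {
  cat("SimulatedProteome:", length(object@sequences), "proteins (",
      length(object@contaminants), "contaminants ),",
      nrow(object@deSpec), "spiked fold changes\n")
})

## average residue frequencies with K+R ~ 11% so tryptic yields are
## realistic; not a claim about real proteomes
.RESIDUE_FREQ <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9,
                   E = 6.8, G = 7.1, H = 2.3, I = 6.0, L = 9.7, K = 5.8,
                   M = 2.4, F = 3.9, P = 4.7, S = 6.6, T = 5.4, W = 1.1,
                   Y = 2.9, V = 6.9)

.datasetDesign <- function() {
  data.frame(
    dataset = c("P1_control", "P1_sds", "P2_control", "P2_sds"),
    protocol = c("deep", "deep", "shallow", "shallow"),
    condition = c("control", "treated", "control", "treated"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic proteome with all static fixtures
#'
#' Random amino-acid sequences with log-uniform lengths, gene symbols,
#' spiked differential / housekeeping / contaminant roles, the nested
#' gene-set fixtures (disease > cellular proliferation > skin cancer >
#' BIR pathway, spiked up-regulated genes innermost), and the per-protein
#' tryptic peptide index used when sampling spectra.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return a \linkS4class{SimulatedProteome}.
#' @export
simulateProteome <- function(params) {
  validObject(params)
  set.seed(params@seed %% 2147483647)
  n <- as.integer(params@nProteins)
  lens <- round(exp(stats::runif(n, log(params@lengthRange[1]),
                                 log(params@lengthRange[2]))))
  residues <- names(.RESIDUE_FREQ)
  seqs <- vapply(lens, function(L)
    paste(sample(residues, L, replace = TRUE, prob = .RESIDUE_FREQ),
          collapse = ""), character(1))
  acc <- sprintf("SYN%04d", seq_len(n))
  names(seqs) <- acc
  w <- stats::rlnorm(n, params@abundanceMeanlog, params@abundanceSdlog)
  names(w) <- acc

  ## role assignment: spiked genes on upper-mid abundance proteins so they
  ## are reliably detected; housekeeping on abundant proteins
  ord <- order(w, decreasing = TRUE)
  genes <- stats::setNames(sprintf("G%04d", seq_len(n)), acc)
  nd <- nrow(params@deSpec)
  deIdx <- ord[unique(round(seq(0.10 * n, 0.35 * n, length.out = nd)))]
  genes[deIdx] <- params@deSpec$gene
  nhk <- length(params@housekeeping)
  hkIdx <- ord[unique(round(seq(0.02 * n, 0.08 * n, length.out = nhk)))]
  genes[hkIdx] <- params@housekeeping

  ## keratin-like contaminants at low random abundance
  contAcc <- paste0("CON_", params@contaminants)
  contLens <- round(stats::runif(length(contAcc), 400, 600))
  contSeqs <- vapply(contLens, function(L)
    paste(sample(residues, L, replace = TRUE, prob = .RESIDUE_FREQ),
          collapse = ""), character(1))
  names(contSeqs) <- contAcc
  contW <- stats::setNames(
    stats::rlnorm(length(contAcc), params@abundanceMeanlog - 2, 0.5),
    contAcc)
  seqs <- c(seqs, contSeqs)
  w <- c(w, contW)
  genes <- c(genes, stats::setNames(params@contaminants, contAcc))

  membrane <- sample(setdiff(acc, acc[c(deIdx, hkIdx)]),
                     round(params@membraneFraction * n))

  ## detectable tryptic peptides (7-30 aa, fully cleaved) per protein, with
  ## a proteome-wide uniqueness flag
  peps <- lapply(seqs, function(s)
    digestTryptic(s, maxMissed = 0L, minLen = 7L, maxLen = 30L))
  allPep <- unlist(lapply(peps, `[[`, "peptide"), use.names = FALSE)
  shared <- unique(allPep[duplicated(allPep)])
  peps <- lapply(peps, function(df) {
    df$unique <- !df$peptide %in% shared
    df
  })

  ## nested gene-set fixtures; up-spiked genes sit in the innermost set
  upGenes <- params@deSpec$gene[params@deSpec$fold > 1]
  downGenes <- params@deSpec$gene[params@deSpec$fold < 1]
  others <- setdiff(unname(genes), c(upGenes, downGenes,
                                     params@housekeeping,
                                     params@contaminants))
  pick <- function(k) sample(others, k)
  bir <- c(upGenes, pick(4))
  skin <- unique(c(bir, downGenes, pick(30)))
  prolif <- unique(c(skin, pick(60)))
  disease <- unique(c(prolif, pick(120)))
  gsc <- GeneSetCollection(list(
    "DOID:4_disease" = disease,
    "DOID:14566_proliferation" = prolif,
    "COSMIC:skin_cancer" = skin,
    "GO:0000727_BIR_pathway" = bir,
    "GO:housekeeping_metabolism" = c(params@housekeeping, pick(25)),
    "GO:random_process_a" = pick(40),
    "GO:random_process_b" = pick(40)),
    sourceTag = "synthetic")

  deSpec <- data.frame(accession = acc[deIdx], gene = params@deSpec$gene,
                       fold = params@deSpec$fold, stringsAsFactors = FALSE)
  new("SimulatedProteome", sequences = seqs, genes = genes,
      abundance = w, membrane = membrane, contaminants = contAcc,
      peptides = peps, geneSets = gsc, deSpec = deSpec, params = params)
}

.repeatSeed <- function(seed, dataset, repeatIndex) {
  dsNum <- match(dataset, .datasetDesign()$dataset)
  as.integer((seed * 1009 + dsNum * 101 + repeatIndex * 7) %% 2147483629)
}

#' Sample one technical repeat's spectral-count report
#'
#' Spectral counts are drawn multinomially at fixed depth with
#' probabilities proportional to abundance x condition fold x protocol
#' bias (the shallow protocol down-weights the membrane-like stratum).
#' Spectra within a protein are spread over its detectable tryptic
#' peptides (probability proportional to peptide length);
#' n_unique_validated_peptides counts distinct sampled proteome-unique
#' peptides and coverage_pct the residues they span. NSAF is left absent:
#' computing it is the pipeline's job.
#'
#' @param proteome a \linkS4class{SimulatedProteome}.
#' @param condition "control" or "treated".
#' @param protocol "deep" or "shallow".
#' @param repeatIndex technical repeat number (seeds the draw).
#' @param dataset dataset label for the report (default from design).
#' @return a \linkS4class{ProteinReport} of the detected proteins.
#' @export
simulateCounts <- function(proteome, condition = c("control", "treated"),
                           protocol = c("deep", "shallow"),
                           repeatIndex = 1L, dataset = NULL) {
  condition <- match.arg(condition)
  protocol <- match.arg(protocol)
  params <- proteome@params
  design <- .datasetDesign()
  if (is.null(dataset))
    dataset <- design$dataset[design$protocol == protocol &
                              design$condition == condition]
  set.seed(.repeatSeed(params@seed, dataset, repeatIndex))
  w <- proteome@abundance
  if (condition == "treated")
    w[proteome@deSpec$accession] <-
      w[proteome@deSpec$accession] * proteome@deSpec$fold
  if (protocol == "shallow")
    w[proteome@membrane] <- w[proteome@membrane] * params@shallowMembraneBias
  depth <- params@depths[[protocol]]
  counts <- as.vector(stats::rmultinom(1, depth, prob = w))
  names(counts) <- names(w)
  det <- which(counts > 0)
  accs <- names(w)[det]
  L <- nchar(proteome@sequences[accs])
  nUniq <- integer(length(det))
  cov <- numeric(length(det))
  for (j in seq_along(det)) {
    pep <- proteome@peptides[[accs[j]]]
    if (nrow(pep)) {
      idx <- unique(sample.int(nrow(pep), counts[det[j]], replace = TRUE,
                               prob = nchar(pep$peptide)))
      nUniq[j] <- sum(pep$unique[idx])
      cov[j] <- 100 * sum(nchar(pep$peptide[idx])) / L[[j]]
    }
  }
  df <- data.frame(accession = accs, gene = unname(proteome@genes[accs]),
                   description = "", coverage_pct = cov,
                   n_unique_validated_peptides = nUniq,
                   spectral_count = unname(counts[det]),
                   nsaf = NA_real_, length_aa = unname(L),
                   stringsAsFactors = FALSE)
  ProteinReport(df, datasetId = dataset,
                repeatLabels = paste0("r", repeatIndex))
}

#' Simulate all four datasets' technical repeats
#'
#' @param proteome a \linkS4class{SimulatedProteome}.
#' @return named list (dataset) of lists of per-repeat
#'   \linkS4class{ProteinReport}s.
#' @export
simulateDatasets <- function(proteome) {
  params <- proteome@params
  design <- .datasetDesign()
  out <- list()
  for (i in seq_len(nrow(design))) {
    ds <- design$dataset[i]
    nr <- params@repeats[[ds]]
    out[[ds]] <- lapply(seq_len(nr), function(r)
      simulateCounts(proteome, design$condition[i], design$protocol[i],
                     repeatIndex = r, dataset = ds))
  }
  out
}

#' Simulate a qPCR Ct plate
#'
#' Target Ct = baseline - log2(group fold) + Normal(0, noiseSd) per
#' technical replicate; reference genes at fold 1 around their own
#' baseline. Groups follow the dose design (control, dose1, dose2) with
#' nBio biological samples each measured in nTech technical replicates.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return data.frame in \code{\link{readQPCRTable}} layout.
#' @export
simulateQPCR <- function(params) {
  q <- params@qpcr
  set.seed(as.integer((params@seed * 1009 + 777) %% 2147483629))
  rows <- list()
  for (g in names(q$groupFolds)) {
    for (b in seq_len(q$nBio)) {
      sid <- paste0(g, "_b", b)
      for (tech in seq_len(q$nTech)) {
        ct_t <- q$baselineCt - log2(q$groupFolds[[g]]) +
          stats::rnorm(1, 0, q$noiseSd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g, target = q$target,
          reference = FALSE, replicate = tech, ct = ct_t,
          stringsAsFactors = FALSE)
        for (r in q$references) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = g, target = r,
            reference = TRUE, replicate = tech,
            ct = q$refCt + stats::rnorm(1, 0, q$noiseSd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate and write every pipeline input
#'
#' Writes the FASTA, accession-to-gene mapping, contaminant list, nested
#' GMT fixtures, per-repeat report TSVs, the qPCR Ct plate and a
#' ground-truth table to \code{outDir}, and returns the file manifest with
#' checksums. Identical params give byte-identical files.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @param outDir output directory.
#' @return invisibly, a list with the proteome, the per-dataset report file
#'   paths and the manifest data.frame.
#' @export
simulateAll <- function(params, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  proteome <- simulateProteome(params)
  datasets <- simulateDatasets(proteome)

  fastaFile <- file.path(outDir, "proteome.fasta")
  aa <- Biostrings::AAStringSet(proteome@sequences)
  names(aa) <- paste0("sp|", names(proteome@sequences), "|",
                      proteome@genes, "_SYN")
  Biostrings::writeXStringSet(aa, fastaFile, width = 60)

  mapFile <- file.path(outDir, "mapping.tsv")
  utils::write.table(
    data.frame(accession = names(proteome@genes),
               gene = unname(proteome@genes)),
    mapFile, sep = "\t", quote = FALSE, row.names = FALSE)

  contFile <- file.path(outDir, "contaminants.txt")
  writeLines(c("# keratin-like contaminants (cRAP-style, synthetic)",
               proteome@contaminants, params@contaminants), contFile)

  gmtFile <- file.path(outDir, "gene_sets.gmt")
  sets <- geneSets(proteome@geneSets)
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "synthetic fixture", sets[[nm]]), collapse = "\t"),
    character(1)), gmtFile)

  reportFiles <- list()
  for (ds in names(datasets)) {
    reportFiles[[ds]] <- vapply(seq_along(datasets[[ds]]), function(r) {
      f <- file.path(outDir, sprintf("report_%s_r%d.tsv", ds, r))
      e <- entries(datasets[[ds]][[r]])
      e <- e[, c("accession", "gene", "description", "coverage_pct",
                 "n_unique_validated_peptides", "spectral_count",
                 "length_aa")]
      utils::write.table(e, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f
    }, character(1))
  }

  qpcrFile <- file.path(outDir, "qpcr.tsv")
  utils::write.table(simulateQPCR(params), qpcrFile, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  gtFile <- file.path(outDir, "ground_truth.tsv")
  gt <- data.frame(accession = names(proteome@genes),
                   gene = unname(proteome@genes),
                   true_fold = 1, role = "background",
                   stringsAsFactors = FALSE)
  gt$true_fold[match(proteome@deSpec$accession, gt$accession)] <-
    proteome@deSpec$fold
  gt$role[match(proteome@deSpec$accession, gt$accession)] <- "spiked"
  gt$role[gt$gene %in% params@housekeeping] <- "housekeeping"
  gt$role[gt$accession %in% proteome@contaminants] <- "contaminant"
  gt$role[gt$accession %in% proteome@membrane] <- paste0(
    gt$role[gt$accession %in% proteome@membrane], "+membrane")
  utils::write.table(gt, gtFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  files <- c(fastaFile, mapFile, contFile, gmtFile,
             unlist(reportFiles, use.names = FALSE), qpcrFile, gtFile)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  invisible(list(proteome = proteome, reports = reportFiles,
                 files = list(fasta = fastaFile, mapping = mapFile,
                              contaminants = contFile, gmt = gmtFile,
                              qpcr = qpcrFile, groundTruth = gtFile),
                 manifest = manifest))
}
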