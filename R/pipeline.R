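## End-to-end orchestration from a single config: read inputs -> QC filters
## -> NSAF quantification -> protocol comparison -> fold-change/gene-set
## funnel (-> qPCR when a Ct plate is given) -> deterministic result export
## with a reproducibility manifest.

#' Build and validate a pipeline configuration
#'
#' @param x a named list or a path to a YAML file. Recognized keys:
#'   \code{reports} (named list dataset -> vector of report TSV paths),
#'   \code{fasta}, \code{gmt}, \code{mapping}, \code{contaminants},
#'   \code{qpcr} (optional Ct table path), \code{out_dir},
#'   \code{pairs} (named list, each c(control=, treated=) dataset names),
#'   \code{funnel_stages} (ordered GMT set names), \code{enrich_collection}
#'   (GMT set names to test, default all), \code{fc_threshold} (default 2),
#'   \code{min_unique_peptides} (default 2), \code{alpha} (default 0.05),
#'   \code{adjust} (default "BH"), \code{qpcr_target},
#'   \code{qpcr_references}, \code{qpcr_control}.
#' @return validated config list (class "PipelineConfig").
#' @export
pipelineConfig <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
  defaults <- list(fc_threshold = 2, min_unique_peptides = 2,
                   alpha = 0.05, adjust = "BH",
                   qpcr_target = "MCM6",
                   qpcr_references = c("GAPDH", "ACTB"),
                   qpcr_control = "control")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  problems <- character()
  need <- c("reports", "fasta", "gmt", "mapping", "contaminants",
            "out_dir", "pairs", "funnel_stages")
  for (nm in need)
    if (is.null(cfg[[nm]]))
      problems <- c(problems, paste0("missing config key: ", nm))
  pathKeys <- c("fasta", "gmt", "mapping", "contaminants", "qpcr")
  for (nm in pathKeys) {
    p <- cfg[[nm]]
    if (!is.null(p) && !file.exists(p))
      problems <- c(problems, paste0(nm, " file not found: ", p))
  }
  for (ds in names(cfg$reports))
    for (p in cfg$reports[[ds]])
      if (!file.exists(p))
        problems <- c(problems, paste0("report file not found: ", p))
  if (cfg$fc_threshold < 1)
    problems <- c(problems, "fc_threshold must be >= 1")
  if (length(problems))
    stop("pipeline config validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  structure(cfg, class = "PipelineConfig")
}

.lengthsFor <- function(entryTab, fastaLengths) {
  out <- fastaLengths
  extra <- setdiff(entryTab$accession, names(out))
  if (length(extra)) {
    fromReport <- entryTab$length_aa[match(extra, entryTab$accession)]
    if (any(is.na(fromReport)))
      stop("no protein length available for: ",
           paste(extra[is.na(fromReport)], collapse = ", "))
    out[extra] <- fromReport
  }
  out
}

.joinRepeats <- function(reports, dataset) {
  ## dataset-level table: counts summed, unique peptides maxed, coverage
  ## averaged over the repeats a protein was seen in
  all <- do.call(rbind, lapply(reports, entries))
  sp <- split(all, all$accession)
  df <- data.frame(
    accession = names(sp),
    gene = vapply(sp, function(d) d$gene[1], character(1)),
    description = "",
    coverage_pct = vapply(sp, function(d)
      mean(d$coverage_pct, na.rm = TRUE), numeric(1)),
    n_unique_validated_peptides = vapply(sp, function(d)
      max(d$n_unique_validated_peptides, na.rm = TRUE), numeric(1)),
    spectral_count = vapply(sp, function(d)
      sum(d$spectral_count, na.rm = TRUE), numeric(1)),
    nsaf = NA_real_,
    length_aa = vapply(sp, function(d) d$length_aa[1], numeric(1)),
    stringsAsFactors = FALSE)
  ProteinReport(df, datasetId = dataset,
                repeatLabels = paste0("r", seq_along(reports)))
}

#' Run the full comparative pipeline
#'
#' Stage order: report reading -> contaminant screen -> minimum-unique-
#' peptide filter (per repeat and on the joined dataset table) -> NSAF ->
#' Venn partition and metric summaries -> pooled t-tests on per-repeat
#' identification counts -> per-pair fold changes -> gene-set funnel and
#' hypergeometric enrichment -> optional delta-delta-Ct. All outputs are
#' written under \code{config$out_dir} along with \code{run_manifest.json}
#' carrying input checksums, the parameter echo and per-stage row counts;
#' a re-run on identical inputs is byte-identical.
#'
#' @param config a \code{\link{pipelineConfig}} (or list/path coercible).
#' @return invisibly, a list with all stage results and the manifest.
#' @export
runPipeline <- function(config) {
  cfg <- if (inherits(config, "PipelineConfig")) config
         else pipelineConfig(config)
  log <- list()
  stage <- function(name, nIn, nOut)
    log[[length(log) + 1L]] <<- data.frame(
      stage = name, n_in = nIn, n_out = nOut, stringsAsFactors = FALSE)

  ## ---- inputs ----
  fasta <- readFastaSequences(cfg$fasta)
  lengths <- stats::setNames(nchar(fasta), names(fasta))
  gmt <- readGMT(cfg$gmt)
  mapping <- readMappingTable(cfg$mapping)
  contaminants <- readContaminantList(cfg$contaminants)
  badStage <- setdiff(cfg$funnel_stages, names(geneSets(gmt)))
  if (length(badStage))
    stop("funnel stage(s) absent from GMT: ",
         paste(badStage, collapse = ", "))

  perRepeat <- list(); joined <- list(); traces <- list()
  repeatCounts <- list()
  for (ds in names(cfg$reports)) {
    reps <- lapply(seq_along(cfg$reports[[ds]]), function(i)
      readProteinReport(cfg$reports[[ds]][i], datasetId = ds,
                        repeatLabels = paste0("r", i)))
    ## identical filters per technical repeat, for identification counts
    filtered <- lapply(reps, function(r) {
      sc <- screenContaminants(r, contaminants, mapping = mapping)
      fp <- filterMinUniquePeptides(sc$report,
                                    k = cfg$min_unique_peptides)
      fp$report
    })
    repeatCounts[[ds]] <- vapply(filtered, function(r)
      nrow(entries(r)), numeric(1))
    perRepeat[[ds]] <- reps
    j <- .joinRepeats(reps, ds)
    n0 <- nrow(entries(j))
    sc <- screenContaminants(j, contaminants, mapping = mapping)
    fp <- filterMinUniquePeptides(sc$report, k = cfg$min_unique_peptides)
    ## NSAF recomputed over the post-filter universe (lengths from FASTA,
    ## falling back to the report's own length column)
    fe <- entries(fp$report)
    nsafTab <- computeNSAF(
      stats::setNames(fe$spectral_count, fe$accession),
      .lengthsFor(fe, lengths))
    fe$nsaf <- nsafTab$nsaf[match(fe$accession, nsafTab$accession)]
    joined[[ds]] <- ProteinReport(fe, ds, repeatLabels(fp$report))
    traces[[ds]] <- rbind(sc$trace, fp$trace)
    stage(paste0("filter:", ds), n0, nrow(entries(fp$report)))
  }

  venn <- vennPartition(joined)
  summaries <- do.call(rbind, lapply(joined, metricSummaries))

  ## pooled t-tests on per-repeat identification counts
  dsn <- names(joined)
  tPairs <- list()
  if (length(dsn) == 4L) {
    combos <- list(c(1, 2), c(3, 4), c(1, 3), c(2, 4))
    for (cb in combos) {
      key <- paste(dsn[cb[1]], "vs", dsn[cb[2]])
      tPairs[[key]] <- pooledTFromReplicates(
        repeatCounts[[dsn[cb[1]]]], repeatCounts[[dsn[cb[2]]]],
        alpha = cfg$alpha)
    }
  }

  ## per protocol pair: NSAF (recomputed over the filtered universe from
  ## counts summed across repeats), fold changes, funnel, enrichment
  pairResults <- list()
  for (pnm in names(cfg$pairs)) {
    pair <- cfg$pairs[[pnm]]
    ctl <- joined[[pair[["control"]]]]
    trt <- joined[[pair[["treated"]]]]
    cp <- commonProteins(ctl, trt)
    nsafC <- computeNSAF(
      stats::setNames(entries(ctl)$spectral_count, accessions(ctl)),
      .lengthsFor(entries(ctl), lengths))
    nsafT <- computeNSAF(
      stats::setNames(entries(trt)$spectral_count, accessions(trt)),
      .lengthsFor(entries(trt), lengths))
    keep <- function(tab) tab[tab$accession %in% cp$shared, , drop = FALSE]
    fc <- foldChanges(keep(nsafC), keep(nsafT),
                      threshold = cfg$fc_threshold, genes = mapping)
    funnel <- runFunnel(fc, geneSets(gmt)[cfg$funnel_stages], mapping)
    universe <- mapToGenes(accessions(ctl), mapping)$genes
    finalGenes <- funnel$genes[[length(funnel$genes)]]
    enrichSets <- if (is.null(cfg$enrich_collection)) geneSets(gmt)
                  else geneSets(gmt)[cfg$enrich_collection]
    enrich <- if (length(finalGenes))
      hypergeomEnrich(finalGenes, universe, enrichSets,
                      adjust = cfg$adjust)
    else NULL
    stage(paste0("funnel:", pnm), nrow(fc),
          length(finalGenes))
    pairResults[[pnm]] <- list(common = cp, fc = fc, funnel = funnel,
                               enrichment = enrich)
  }

  qpcrRes <- NULL
  if (!is.null(cfg$qpcr)) {
    qtab <- readQPCRTable(cfg$qpcr)
    qpcrRes <- deltaDeltaCt(qtab, target = cfg$qpcr_target,
                            references = cfg$qpcr_references,
                            controlGroup = cfg$qpcr_control)
    stage("qpcr", nrow(qtab), nrow(qpcrRes$groups))
  }

  ## ---- export ----
  outTables <- list(venn_sizes = venn$sizes, metric_summaries = summaries,
                    filter_trace = do.call(rbind, traces))
  for (pnm in names(pairResults)) {
    pr <- pairResults[[pnm]]
    outTables[[paste0("fc_", pnm)]] <- pr$fc
    outTables[[paste0("funnel_", pnm)]] <- pr$funnel$stages
    if (!is.null(pr$enrichment))
      outTables[[paste0("enrichment_", pnm)]] <- pr$enrichment
  }
  if (length(tPairs))
    outTables$t_tests <- do.call(rbind, lapply(names(tPairs), function(k) {
      r <- tPairs[[k]]
      data.frame(comparison = k, t = r$t, df = r$df, p = r$p,
                 stringsAsFactors = FALSE)
    }))
  if (!is.null(qpcrRes)) outTables$qpcr_groups <- qpcrRes$groups
  manifest <- writeResultTables(outTables, cfg$out_dir)

  inputFiles <- c(cfg$fasta, cfg$gmt, cfg$mapping, cfg$contaminants,
                  cfg$qpcr, unlist(cfg$reports, use.names = FALSE))
  runManifest <- list(
    parameters = cfg[c("fc_threshold", "min_unique_peptides", "alpha",
                       "adjust", "funnel_stages")],
    stages = do.call(rbind, log),
    inputs = data.frame(file = basename(inputFiles),
                        md5 = unname(tools::md5sum(inputFiles)),
                        stringsAsFactors = FALSE),
    outputs = manifest)
  jsonlite::write_json(runManifest,
                       file.path(cfg$out_dir, "run_manifest.json"),
                       dataframe = "rows", pretty = TRUE,
                       auto_unbox = TRUE)
  invisible(list(joined = joined, venn = venn, summaries = summaries,
                 tTests = tPairs, pairs = pairResults, qpcr = qpcrRes,
                 manifest = runManifest))
}
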