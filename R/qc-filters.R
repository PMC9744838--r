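## Validation filters and annotation subsets: minimum unique validated
## peptides, contaminant screening, gene-subset flags, housekeeping panel.
## Every filter returns the filtered report plus a FilterTrace step so the
## chain reconstructs exactly which rule removed each accession.

.traceStep <- function(name, nIn, nOut, removed) {
  data.frame(filter = name, n_in = nIn, n_out = nOut,
             removed = paste(removed, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Retain proteins identified by at least k unique validated peptides
#'
#' @param report a \linkS4class{ProteinReport}.
#' @param k minimum number of unique validated peptides (default 2).
#' @return list with elements \code{report} (filtered) and \code{trace}
#'   (one FilterTrace row).
#' @export
filterMinUniquePeptides <- function(report, k = 2L) {
  if (k < 1) stop("k must be >= 1")
  e <- entries(report)
  keep <- !is.na(e$n_unique_validated_peptides) &
    e$n_unique_validated_peptides >= k
  removed <- e$accession[!keep]
  out <- ProteinReport(e[keep, , drop = FALSE], datasetId(report),
                       repeatLabels(report))
  list(report = out,
       trace = .traceStep(sprintf("min_unique_peptides>=%d", k),
                          nrow(e), sum(keep), removed))
}

#' Screen a report for contaminants
#'
#' Matches entries against a cRAP-style contaminant list on accession or on
#' gene symbol (the entry's own gene column plus, when given, a mapping
#' table). Matching entries are removed by default and reported by gene.
#'
#' @param report a \linkS4class{ProteinReport}.
#' @param contaminants character vector of accessions or gene symbols.
#' @param mapping optional named vector accession -> gene.
#' @param action "remove" (default) or "report" (flag only).
#' @return list with elements \code{report}, \code{trace}, \code{found}
#'   (gene symbols, or accessions if no gene known, of matches).
#' @export
screenContaminants <- function(report, contaminants, mapping = NULL,
                               action = c("remove", "report")) {
  action <- match.arg(action)
  e <- entries(report)
  cont <- toupper(contaminants)
  gene <- toupper(e$gene)
  if (!is.null(mapping)) {
    mapped <- toupper(mapping[e$accession])
    gene <- ifelse(nzchar(gene), gene,
                   ifelse(is.na(mapped), "", mapped))
  }
  hit <- toupper(e$accession) %in% cont | (nzchar(gene) & gene %in% cont)
  found <- ifelse(nzchar(gene[hit]), gene[hit], e$accession[hit])
  keep <- if (action == "remove") !hit else rep(TRUE, nrow(e))
  out <- ProteinReport(e[keep, , drop = FALSE], datasetId(report),
                       repeatLabels(report))
  list(report = out,
       trace = .traceStep("contaminant_screen", nrow(e), sum(keep),
                          e$accession[hit]),
       found = unname(found))
}

#' Flag report entries belonging to a gene subset
#'
#' Adds a logical column \code{in_<label>} to the entry table. Accessions
#' without a gene (own column or mapping) get FALSE and are counted as
#' unmapped.
#'
#' @param report a \linkS4class{ProteinReport}.
#' @param subset character vector of gene symbols (e.g. one set of a
#'   \linkS4class{GeneSetCollection}).
#' @param label subset label used for the flag column.
#' @param mapping optional named vector accession -> gene.
#' @return list with \code{report} (annotated), \code{nFlagged},
#'   \code{unmapped} (accessions lacking a gene).
#' @export
annotateSubset <- function(report, subset, label, mapping = NULL) {
  e <- entries(report)
  subset <- toupper(subset)
  gene <- toupper(e$gene)
  if (!is.null(mapping)) {
    mapped <- toupper(mapping[e$accession])
    gene <- ifelse(nzchar(gene), gene, ifelse(is.na(mapped), "", mapped))
  }
  unmapped <- e$accession[!nzchar(gene)]
  flag <- nzchar(gene) & gene %in% subset
  e[[paste0("in_", label)]] <- flag
  list(report = ProteinReport(e, datasetId(report), repeatLabels(report)),
       nFlagged = sum(flag), unmapped = unmapped)
}

#' Extract NSAF values for a housekeeping panel
#'
#' One row per (gene, sample); panel members absent from a sample are
#' flagged missing rather than dropped.
#'
#' @param nsafTables named list of data.frames from
#'   \code{\link{computeNSAF}} (names are sample labels).
#' @param panel character vector of panel gene symbols.
#' @param mapping named vector accession -> gene.
#' @return data.frame with columns gene, sample, accession, nsaf, missing.
#' @export
housekeepingPanel <- function(nsafTables, panel, mapping) {
  if (is.null(names(nsafTables))) stop("nsafTables must be named by sample")
  panel <- toupper(panel)
  geneByAcc <- toupper(mapping)
  rows <- list()
  for (smp in names(nsafTables)) {
    tab <- nsafTables[[smp]]
    tabGenes <- geneByAcc[tab$accession]
    for (g in panel) {
      i <- which(!is.na(tabGenes) & tabGenes == g)
      if (length(i)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, sample = smp, accession = tab$accession[i[1]],
          nsaf = tab$nsaf[i[1]], missing = FALSE, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, sample = smp, accession = NA_character_,
          nsaf = NA_real_, missing = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
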