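## Readers and writers for every external artifact the pipeline touches:
## identification reports (TSV/CSV), FASTA, GMT gene sets, accession->gene
## mapping tables, contaminant lists, qPCR Ct plates, and TSV/JSON exports.

.read_delim_strict <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE, na.strings = c("NA", ""))
}

#' Read a protein-level identification report
#'
#' Ingests a delimited protein report (one row per protein) in the style of
#' PeptideShaker exports saved as text. The header must contain at least
#' \code{accession}, \code{n_unique_validated_peptides}, and one of
#' \code{spectral_count} / \code{nsaf}. Optional columns (\code{gene},
#' \code{description}, \code{coverage_pct}, \code{length_aa}) are parsed when
#' present and flagged absent (\code{NA}) otherwise. Decimal parsing is
#' locale-independent (dot).
#'
#' @param path file path.
#' @param dialect "tsv" (default) or "csv".
#' @param datasetId dataset label; defaults to the file name sans extension.
#' @param repeatLabels repeat labels covered by the file.
#' @return a \linkS4class{ProteinReport}.
#' @export
readProteinReport <- function(path, dialect = c("tsv", "csv"),
                              datasetId = NULL, repeatLabels = "joined") {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- match.arg(dialect)
  if (is.null(datasetId))
    datasetId <- sub("\\.[^.]*$", "", basename(path))
  df <- .read_delim_strict(path, dialect)
  mandatory <- c("accession", "n_unique_validated_peptides")
  miss <- setdiff(mandatory, colnames(df))
  if (length(miss))
    stop("report schema error: missing mandatory column(s) ",
         paste(miss, collapse = ", "), " in ", path)
  if (!any(c("spectral_count", "nsaf") %in% colnames(df)))
    stop("report schema error: need at least one of 'spectral_count', ",
         "'nsaf' in ", path)
  dup <- unique(df$accession[duplicated(df$accession)])
  if (length(dup))
    stop("report validation error: duplicate accession(s): ",
         paste(dup, collapse = ", "))
  num_cols <- intersect(c("coverage_pct", "n_unique_validated_peptides",
                          "spectral_count", "nsaf", "length_aa"),
                        colnames(df))
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad))
        stop("parse error in column '", col, "', data row(s) ",
             paste(bad, collapse = ", "), " of ", path)
      df[[col]] <- parsed
    }
  }
  ProteinReport(df, datasetId = datasetId, repeatLabels = repeatLabels)
}

#' Read a GMT gene-set file
#'
#' Each line is \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Genes are
#' uppercased and deduplicated per set; empty sets and duplicate set names
#' are rejected.
#'
#' @param path file path.
#' @param sourceTag provenance tag stored on the collection.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path, sourceTag = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": expected >= 3 tab-separated ",
           "fields, got ", length(f))
    nm <- f[[1]]
    if (nm %in% names(sets))
      stop("GMT parse error: duplicate set name '", nm, "' at line ", i)
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("GMT parse error: set '", nm, "' at line ", i, " has no genes")
    sets[[nm]] <- genes
  }
  GeneSetCollection(sets, sourceTag = sourceTag)
}

#' Read protein sequences from FASTA
#'
#' UniProt-style headers \code{sp|ACC|NAME} yield the second pipe-delimited
#' token as the accession; bare headers yield the first whitespace-delimited
#' token. Sequences are uppercased. Sequences containing characters outside
#' the 20 canonical residues are retained with a warning (mass operations
#' reject them later).
#'
#' @param path FASTA file path.
#' @return named character vector, accession -> amino-acid sequence.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("empty or missing FASTA file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("empty FASTA file: ", path)
  headers <- names(aa)
  acc <- vapply(headers, function(h) {
    first <- strsplit(h, "\\s+")[[1]][1]
    if (grepl("|", first, fixed = TRUE)) {
      tok <- strsplit(first, "|", fixed = TRUE)[[1]]
      if (length(tok) >= 2) tok[[2]] else tok[[1]]
    } else first
  }, character(1), USE.NAMES = FALSE)
  dup <- unique(acc[duplicated(acc)])
  if (length(dup))
    stop("duplicate FASTA accession(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(aa))
  names(seqs) <- acc
  bad <- grepl(sprintf("[^%s]", paste(names(.residueMasses()), collapse = "")),
               seqs)
  if (any(bad))
    warning("non-canonical residues in: ",
            paste(acc[bad], collapse = ", "), " (entries retained)")
  seqs
}

#' Read an accession-to-gene mapping table
#'
#' Two-column TSV (accession, gene). On accession collision the first row
#' wins and a warning lists the collisions.
#'
#' @param path file path.
#' @return named character vector, accession -> uppercase gene symbol.
#' @export
readMappingTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("mapping table needs two columns (accession, gene)")
  acc <- as.character(df[[1]])
  gene <- toupper(as.character(df[[2]]))
  dup <- duplicated(acc)
  if (any(dup)) {
    warning("mapping collisions (first wins): ",
            paste(unique(acc[dup]), collapse = ", "))
    gene <- gene[!dup]
    acc <- acc[!dup]
  }
  stats::setNames(gene, acc)
}

#' Read a contaminant list (cRAP-style)
#'
#' One accession or gene symbol per line; \code{#} starts a comment.
#'
#' @param path file path.
#' @return character vector of identifiers.
#' @export
readContaminantList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Read a qPCR Ct table
#'
#' TSV with columns \code{sample_id}, \code{group}, \code{target},
#' \code{reference} (TRUE/FALSE), \code{replicate}, \code{ct}.
#'
#' @param path file path.
#' @return data.frame with validated columns.
#' @export
readQPCRTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "target", "reference", "replicate", "ct")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("qPCR table missing column(s): ", paste(miss, collapse = ", "))
  ct <- suppressWarnings(as.numeric(df$ct))
  bad <- which(is.na(ct) | ct <= 0)
  if (length(bad))
    stop("qPCR parse error: non-numeric or non-positive Ct at data row(s) ",
         paste(bad, collapse = ", "))
  df$ct <- ct
  df$reference <- as.logical(df$reference)
  df
}

#' Write named result tables and a manifest
#'
#' Writes each table as \code{<name>.tsv} with a fixed column order (the
#' table's own), plus \code{manifest.json} listing file, row count and md5
#' checksum for each artifact. File naming and content are deterministic so
#' repeated runs on identical inputs are byte-identical.
#'
#' @param tables named list of data.frames.
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
writeResultTables <- function(tables, outDir) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("every table must be named")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  manifest <- data.frame(file = character(), rows = integer(),
                         md5 = character(), stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    f <- file.path(outDir, paste0(nm, ".tsv"))
    df <- as.data.frame(tables[[nm]])
    listcols <- vapply(df, is.list, logical(1))
    for (col in names(df)[listcols])
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ",")
    utils::write.table(df, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    manifest <- rbind(manifest, data.frame(
      file = basename(f), rows = nrow(df),
      md5 = unname(tools::md5sum(f)), stringsAsFactors = FALSE))
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
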