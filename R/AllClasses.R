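#' @import methods
NULL

#' ProteinReport: one dataset's protein-level identification table
#'
#' Container for a protein-level identification report as exported by
#' search-engine integrators (one row per protein with validated evidence
#' metrics). The accession is the primary key; gene symbols only enter
#' downstream at the mapping stage.
#'
#' @slot datasetId single string naming the dataset (protocol x condition,
#'   e.g. "P1_control").
#' @slot repeatLabels character vector of technical-repeat labels covered by
#'   this report (may be a single joined repeat).
#' @slot entries data.frame with columns \code{accession}, \code{gene},
#'   \code{description}, \code{coverage_pct}, \code{n_unique_validated_peptides},
#'   \code{spectral_count}, \code{nsaf}, \code{length_aa}. Optional metrics
#'   that were absent in the source file are \code{NA}, never zero.
#'
#' @export
setClass("ProteinReport",
  representation(
    datasetId    = "character",
    repeatLabels = "character",
    entries      = "data.frame"
  )
)

.REPORT_COLUMNS <- c("accession", "gene", "description", "coverage_pct",
                     "n_unique_validated_peptides", "spectral_count",
                     "nsaf", "length_aa")

setValidity("ProteinReport", function(object) {
  msg <- character()
  e <- object@entries
  if (length(object@datasetId) != 1L || !nzchar(object@datasetId))
    msg <- c(msg, "datasetId must be a single non-empty string")
  if (anyDuplicated(object@repeatLabels))
    msg <- c(msg, "repeat labels must be unique")
  missing_cols <- setdiff(.REPORT_COLUMNS, colnames(e))
  if (length(missing_cols))
    msg <- c(msg, paste0("entries lacks column(s): ",
                         paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols) && nrow(e)) {
    if (any(!nzchar(e$accession)))
      msg <- c(msg, "accessions must be non-empty")
    dup <- unique(e$accession[duplicated(e$accession)])
    if (length(dup))
      msg <- c(msg, paste0("duplicate accession(s): ",
                           paste(dup, collapse = ", ")))
    cv <- e$coverage_pct
    if (any(!is.na(cv) & (cv < 0 | cv > 100)))
      msg <- c(msg, "coverage_pct must lie in [0, 100]")
    np <- e$n_unique_validated_peptides
    if (any(!is.na(np) & np < 0))
      msg <- c(msg, "n_unique_validated_peptides must be >= 0")
    sc <- e$spectral_count
    if (any(!is.na(sc) & sc < 0))
      msg <- c(msg, "spectral_count must be >= 0")
    if (any(!is.na(e$nsaf) & e$nsaf < 0))
      msg <- c(msg, "nsaf must be >= 0")
    if (any(!is.na(e$length_aa) & e$length_aa <= 0))
      msg <- c(msg, "length_aa must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinReport
#'
#' @param entries data.frame of protein rows; missing optional columns are
#'   added as \code{NA}.
#' @param datasetId dataset label.
#' @param repeatLabels technical-repeat labels (default a single "joined").
#' @return a \linkS4class{ProteinReport}.
#' @export
ProteinReport <- function(entries, datasetId, repeatLabels = "joined") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  for (col in .REPORT_COLUMNS) {
    if (!col %in% colnames(entries)) {
      entries[[col]] <- if (col %in% c("accession", "gene", "description"))
        NA_character_ else NA_real_
    }
  }
  if (nrow(entries) && any(is.na(entries$accession)))
    stop("every entry needs an accession")
  entries$gene[is.na(entries$gene)] <- ""
  entries$description[is.na(entries$description)] <- ""
  entries <- entries[, union(.REPORT_COLUMNS, colnames(entries)), drop = FALSE]
  rownames(entries) <- NULL
  new("ProteinReport", datasetId = as.character(datasetId),
      repeatLabels = as.character(repeatLabels), entries = entries)
}

#' GeneSetCollection: named gene sets (GMT-style)
#'
#' @slot sets named list; each element a character vector of uppercase gene
#'   symbols.
#' @slot sourceTag free-text provenance tag (e.g. "synthetic-DO").
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", sourceTag = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) ||
      any(!nzchar(names(object@sets))))
    msg <- c(msg, "every gene set must be named")
  if (anyDuplicated(names(object@sets)))
    msg <- c(msg, "gene set names must be unique")
  for (nm in names(object@sets)) {
    g <- object@sets[[nm]]
    if (!length(g))
      msg <- c(msg, paste0("gene set '", nm, "' is empty"))
    else if (any(!nzchar(g)) || any(g != toupper(g)))
      msg <- c(msg, paste0("gene set '", nm,
                           "' must contain non-empty uppercase symbols"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#' @param sets named list of character vectors (deduplicated, uppercased).
#' @param sourceTag provenance tag.
#' @export
GeneSetCollection <- function(sets, sourceTag = "unspecified") {
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  new("GeneSetCollection", sets = sets, sourceTag = sourceTag)
}

## ---- accessors ----

#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))
#' @export
setGeneric("repeatLabels", function(x) standardGeneric("repeatLabels"))
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @export
setGeneric("sourceTag", function(x) standardGeneric("sourceTag"))

#' @describeIn ProteinReport dataset label.
#' @param x a ProteinReport.
#' @export
setMethod("datasetId", "ProteinReport", function(x) x@datasetId)
#' @describeIn ProteinReport technical-repeat labels.
#' @export
setMethod("repeatLabels", "ProteinReport", function(x) x@repeatLabels)
#' @describeIn ProteinReport the entry table.
#' @export
setMethod("entries", "ProteinReport", function(x) x@entries)
#' @describeIn ProteinReport accession vector.
#' @export
setMethod("accessions", "ProteinReport", function(x) x@entries$accession)
#' @describeIn GeneSetCollection the named list of sets.
#' @param x a GeneSetCollection.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)
#' @describeIn GeneSetCollection provenance tag.
#' @export
setMethod("sourceTag", "GeneSetCollection", function(x) x@sourceTag)

setMethod("show", "ProteinReport", function(object) {
  e <- object@entries
  cat("ProteinReport '", object@datasetId, "': ", nrow(e), " proteins, ",
      length(object@repeatLabels), " repeat(s)\n", sep = "")
  if (nrow(e)) {
    with_sc <- sum(!is.na(e$spectral_count))
    cat("  spectral counts for ", with_sc, " proteins; median unique peptides ",
        stats::median(e$n_unique_validated_peptides, na.rm = TRUE), "\n",
        sep = "")
  }
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection [", object@sourceTag, "]: ",
      length(object@sets), " set(s)\n", sep = "")
  n <- utils::head(names(object@sets), 5)
  for (nm in n)
    cat("  ", nm, " (", length(object@sets[[nm]]), " genes)\n", sep = "")
  if (length(object@sets) > 5) cat("  ...\n")
})
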