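## Staged candidate-selection funnel: fold-change selection -> gene mapping
## -> disease-ontology intersection -> cancer-census intersection -> pathway
## enrichment by exact hypergeometric test over GMT collections.

#' Map accessions to gene symbols
#'
#' @param accs accession character vector.
#' @param mapping named vector accession -> gene.
#' @return list with \code{genes} (deduplicated uppercase set) and
#'   \code{unmapped} (accessions absent from the mapping).
#' @export
mapToGenes <- function(accs, mapping) {
  if (!length(mapping)) stop("empty mapping table")
  g <- mapping[accs]
  unmapped <- accs[is.na(g)]
  list(genes = unique(toupper(g[!is.na(g)])), unmapped = unmapped)
}

#' Run the staged gene-set funnel
#'
#' Starting from the thresholded fold-change table, maps accessions to
#' genes and intersects sequentially with each stage set (e.g. disease
#' ontology root, disease of cellular proliferation, cancer-census skin
#' cancer). Stage k's input is stage k-1's retained set; up/down direction
#' is carried through.
#'
#' @param fcTable data.frame from \code{\link{foldChanges}}; only rows with
#'   direction != "unchanged" enter the funnel.
#' @param stages named list of gene sets (character vectors), applied in
#'   order, or a \linkS4class{GeneSetCollection}.
#' @param mapping named vector accession -> gene.
#' @return list with \code{stages} (data.frame stage/n_in/n_retained),
#'   \code{genes} (named list of retained genes per stage, including the
#'   initial "selected" stage), and \code{direction} (named vector
#'   gene -> up/down for the selected genes).
#' @export
runFunnel <- function(fcTable, stages, mapping) {
  if (is(stages, "GeneSetCollection")) stages <- geneSets(stages)
  if (!length(stages)) stop("stages must be non-empty")
  empty <- names(stages)[lengths(stages) == 0]
  if (length(empty)) stop("empty stage set(s): ",
                          paste(empty, collapse = ", "))
  sel <- fcTable[fcTable$direction != "unchanged", , drop = FALSE]
  mapped <- mapToGenes(sel$accession, mapping)
  current <- mapped$genes
  direction <- stats::setNames(
    sel$direction[match(current, toupper(mapping[sel$accession]))], current)
  geneLists <- list(selected = current)
  rows <- list(data.frame(stage = "selected", n_in = nrow(sel),
                          n_retained = length(current),
                          stringsAsFactors = FALSE))
  for (nm in names(stages)) {
    kept <- intersect(current, toupper(stages[[nm]]))
    rows[[length(rows) + 1L]] <- data.frame(
      stage = nm, n_in = length(current), n_retained = length(kept),
      stringsAsFactors = FALSE)
    geneLists[[nm]] <- kept
    current <- kept
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(stages = out, genes = geneLists,
       direction = direction, unmapped = mapped$unmapped)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided (upper-tail) hypergeometric test of a query gene list against
#' each set of a collection, within a finite universe:
#' p = P(X >= k), X ~ Hypergeometric(N, K, n) with N the universe size, K
#' the set members in the universe, n the query size and k the overlap.
#' Sets with k = 0 are reported with p = 1. Adjustment is applied across
#' the collection's tested sets.
#'
#' @param query gene character vector (genes outside the universe are
#'   dropped with a warning).
#' @param universe gene character vector.
#' @param collection a \linkS4class{GeneSetCollection} or named list.
#' @param adjust "BH" (default), "bonferroni" or "none".
#' @return data.frame with columns set, N, K, n, k, p, p_adj, overlap,
#'   sorted by p ascending.
#' @export
hypergeomEnrich <- function(query, universe, collection,
                            adjust = c("BH", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  sets <- if (is(collection, "GeneSetCollection")) geneSets(collection)
          else collection
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  if (length(universe) < length(query))
    stop("universe smaller than query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(toupper(sets[[nm]]), universe)
    K <- length(members)
    ov <- intersect(query, members)
    k <- length(ov)
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, N = N, K = K, n = n, k = k, p = p,
               overlap = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  method <- c(BH = "BH", bonferroni = "bonferroni", none = "none")[adjust]
  df$p_adj <- stats::p.adjust(df$p, method = method)
  df <- df[order(df$p, df$set), c("set", "N", "K", "n", "k", "p",
                                  "p_adj", "overlap")]
  rownames(df) <- NULL
  df
}

#' Per-repeat set-overlap profiles
#'
#' For each gene set, the fraction of each repeat's mapped gene list falling
#' in the set, with mean and SD (n-1 denominator) across repeats; the
#' numeric surface behind per-category enrichment bar profiles with error
#' bars.
#'
#' @param repeatGeneLists list (length >= 2 for an SD) of gene character
#'   vectors, one per technical repeat.
#' @param collection a \linkS4class{GeneSetCollection} or named list.
#' @return data.frame with columns set, mean_fraction, sd_fraction,
#'   n_repeats; sd is NA when only one repeat is given.
#' @export
enrichmentProfile <- function(repeatGeneLists, collection) {
  sets <- if (is(collection, "GeneSetCollection")) geneSets(collection)
          else collection
  nr <- length(repeatGeneLists)
  if (nr < 1) stop("need at least one repeat")
  fr <- vapply(names(sets), function(nm) {
    s <- toupper(sets[[nm]])
    vapply(repeatGeneLists, function(g) {
      g <- unique(toupper(g))
      if (!length(g)) return(0)
      length(intersect(g, s)) / length(g)
    }, numeric(1))
  }, numeric(nr))
  if (nr == 1L) fr <- matrix(fr, nrow = 1L, dimnames = list(NULL, names(sets)))
  data.frame(set = names(sets),
             mean_fraction = colMeans(fr),
             sd_fraction = if (nr >= 2) apply(fr, 2, stats::sd) else NA_real_,
             n_repeats = nr, stringsAsFactors = FALSE, row.names = NULL)
}
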