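## NSAF quantification and fold-change computation: the quantitative core.
## NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j); values sum to 1 per sample.

#' Compute normalized spectral abundance factors for one sample
#'
#' SAF_i = SpC_i / L_i; NSAF_i = SAF_i / sum(SAF). Proteins with zero
#' spectral count get NSAF 0 and are retained, so the normalization is over
#' the full supplied protein universe.
#'
#' @param counts named numeric vector, accession -> spectral count (>= 0).
#' @param lengths named numeric vector, accession -> protein length in aa.
#' @return data.frame with columns accession, spc, length_aa, saf, nsaf.
#' @export
computeNSAF <- function(counts, lengths) {
  if (is.null(names(counts))) stop("counts must be named by accession")
  if (any(counts < 0)) stop("spectral counts must be >= 0")
  miss <- setdiff(names(counts), names(lengths))
  if (length(miss))
    stop("missing protein length for accession(s): ",
         paste(miss, collapse = ", "))
  L <- lengths[names(counts)]
  if (any(L <= 0)) stop("protein lengths must be > 0")
  if (all(counts == 0)) stop("all spectral counts are zero")
  saf <- counts / L
  nsaf <- saf / sum(saf)
  data.frame(accession = names(counts), spc = as.numeric(counts),
             length_aa = as.numeric(L), saf = as.numeric(saf),
             nsaf = as.numeric(nsaf), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Proteins common to two reports
#'
#' Set intersection on accession, with the off-diagonal sizes reported.
#'
#' @param a,b \linkS4class{ProteinReport} objects or accession character
#'   vectors.
#' @return list with elements shared, aOnly, bOnly (accession vectors) and
#'   sizes (named integer vector).
#' @export
commonProteins <- function(a, b) {
  accOf <- function(x) if (is(x, "ProteinReport")) accessions(x)
                       else as.character(x)
  A <- unique(accOf(a)); B <- unique(accOf(b))
  shared <- intersect(A, B)
  list(shared = shared, aOnly = setdiff(A, B), bOnly = setdiff(B, A),
       sizes = c(shared = length(shared),
                 a_only = length(setdiff(A, B)),
                 b_only = length(setdiff(B, A))))
}

#' NSAF fold changes between two conditions
#'
#' Ratios treated/control over the proteins present in both NSAF tables;
#' proteins with NSAF 0 in the control are excluded with a warning (no
#' ratio can be formed). Direction is "up" iff fc >= threshold, "down" iff
#' fc <= 1/threshold, else "unchanged". Rows are sorted by |log2 fc|
#' descending.
#'
#' @param nsafControl,nsafTreated data.frames from \code{\link{computeNSAF}}
#'   or named NSAF vectors.
#' @param threshold fold-change threshold (>= 1, default 2).
#' @param genes optional named vector accession -> gene symbol.
#' @return data.frame with columns accession, gene, nsaf_control,
#'   nsaf_treated, fc, log2fc, direction.
#' @export
foldChanges <- function(nsafControl, nsafTreated, threshold = 2,
                        genes = NULL) {
  if (threshold < 1) stop("threshold must be >= 1")
  asVec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$nsaf, x$accession) else x
  }
  ctl <- asVec(nsafControl); trt <- asVec(nsafTreated)
  common <- intersect(names(ctl), names(trt))
  ctl <- ctl[common]; trt <- trt[common]
  zero <- ctl == 0
  if (any(zero)) {
    warning(sum(zero), " common protein(s) with control NSAF 0 excluded ",
            "from fold-change table")
    ctl <- ctl[!zero]; trt <- trt[!zero]
    common <- common[!zero]
  }
  fc <- trt / ctl
  direction <- ifelse(fc >= threshold, "up",
                      ifelse(fc <= 1 / threshold, "down", "unchanged"))
  g <- if (is.null(genes)) rep("", length(common))
       else unname(ifelse(is.na(genes[common]), "", genes[common]))
  df <- data.frame(accession = common, gene = g,
                   nsaf_control = as.numeric(ctl),
                   nsaf_treated = as.numeric(trt),
                   fc = as.numeric(fc), log2fc = log2(as.numeric(fc)),
                   direction = direction, stringsAsFactors = FALSE)
  df <- df[order(-abs(df$log2fc), df$accession), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Sum spectral counts over technical repeats
#'
#' Collapses a list of per-repeat \linkS4class{ProteinReport}s of one
#' dataset into a single named count vector (absent = 0 in that repeat).
#'
#' @param reports list of ProteinReport objects.
#' @return named numeric vector, accession -> summed spectral count.
#' @export
sumReportCounts <- function(reports) {
  if (!length(reports)) stop("no reports supplied")
  acc <- unique(unlist(lapply(reports, accessions)))
  total <- stats::setNames(numeric(length(acc)), acc)
  for (r in reports) {
    e <- entries(r)
    sc <- e$spectral_count
    if (all(is.na(sc)))
      stop("report '", datasetId(r), "' has no spectral counts; ",
           "NSAF recomputation is blocked")
    sc[is.na(sc)] <- 0
    total[e$accession] <- total[e$accession] + sc
  }
  total
}
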