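## Protocol/condition comparison: multi-set Venn partitioning, distribution
## summaries of identification metrics, and pooled-variance (Student)
## two-sample t-tests on identification counts, from replicate vectors or
## from printed summary statistics.

#' Exact Venn partition of 2-4 protein reports
#'
#' Every accession is assigned to exactly one region: the subset of datasets
#' it occurs in. Regions are keyed by dataset names joined with "&".
#'
#' @param reports named list of 2-4 \linkS4class{ProteinReport}s or
#'   accession vectors; unnamed lists use dataset ids.
#' @return list with \code{regions} (named list of accession vectors) and
#'   \code{sizes} (data.frame region/size).
#' @export
vennPartition <- function(reports) {
  if (length(reports) < 2 || length(reports) > 4)
    stop("vennPartition needs 2-4 reports")
  accOf <- function(x) if (is(x, "ProteinReport")) accessions(x)
                       else as.character(x)
  if (is.null(names(reports)))
    names(reports) <- vapply(reports, function(x)
      if (is(x, "ProteinReport")) datasetId(x) else "", character(1))
  sets <- lapply(reports, function(x) unique(accOf(x)))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  key <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  regions <- split(universe, key)
  sizes <- data.frame(region = names(regions),
                      size = lengths(regions),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(regions = regions, sizes = sizes)
}

#' Distribution summaries of identification metrics
#'
#' Mean, median, quartiles and n per metric, the numeric surface behind
#' violin-plot style comparisons of reports.
#'
#' @param report a \linkS4class{ProteinReport}.
#' @param metrics entry columns to summarize.
#' @return data.frame with one row per available metric.
#' @export
metricSummaries <- function(report,
                            metrics = c("coverage_pct",
                                        "n_unique_validated_peptides",
                                        "nsaf")) {
  e <- entries(report)
  rows <- list()
  for (m in metrics) {
    v <- e[[m]]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("metric '", m, "' absent for all entries; skipped")
      next
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    rows[[m]] <- data.frame(
      dataset = datasetId(report), metric = m, n = length(v),
      mean = mean(v), median = q[2], q1 = q[1], q3 = q[3],
      min = min(v), max = max(v), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Classic Student test for two small unequal samples given only means,
#' sample SDs (n-1 denominator) and sizes:
#' sp^2 = ((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2),
#' t = (m1-m2) / (sp * sqrt(1/n1 + 1/n2)), two-tailed p on n1+n2-2 df.
#'
#' @param m1,s1,n1 mean, SD and size of sample 1.
#' @param m2,s2,n2 mean, SD and size of sample 2.
#' @param alpha significance level carried on the result (default 0.05).
#' @return list of class "TTestResult" with m1, s1, n1, m2, s2, n2, sp, df,
#'   t, p, alpha, significant.
#' @export
pooledTFromSummary <- function(m1, s1, n1, m2, s2, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("both samples need n >= 2")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  if (sp == 0) {
    if (m1 == m2) {
      t <- 0; p <- 1
    } else stop("degenerate: zero pooled SD with unequal means")
  } else {
    t <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(m1 = m1, s1 = s1, n1 = n1, m2 = m2, s2 = s2, n2 = n2,
                 sp = sp, df = df, t = t, p = p, alpha = alpha,
                 significant = p < alpha),
            class = "TTestResult")
}

#' Pooled-variance t-test from per-replicate counts
#'
#' Computes sample means and SDs (n-1 denominator) and delegates to
#' \code{\link{pooledTFromSummary}}.
#'
#' @param counts1,counts2 numeric vectors of per-repeat identification
#'   counts, length >= 2.
#' @param alpha significance level.
#' @return a "TTestResult" (see \code{\link{pooledTFromSummary}}).
#' @export
pooledTFromReplicates <- function(counts1, counts2, alpha = 0.05) {
  if (length(counts1) < 2 || length(counts2) < 2)
    stop("both replicate vectors need length >= 2")
  pooledTFromSummary(mean(counts1), stats::sd(counts1), length(counts1),
                     mean(counts2), stats::sd(counts2), length(counts2),
                     alpha = alpha)
}

#' @export
print.TTestResult <- function(x, ...) {
  cat(sprintf(
    "Pooled two-sample t-test: t = %.3f, df = %d, p = %.4g (alpha %.2f)\n",
    x$t, x$df, x$p, x$alpha))
  cat(sprintf("  sample 1: %.4g +/- %.4g (n = %d)\n", x$m1, x$s1, x$n1))
  cat(sprintf("  sample 2: %.4g +/- %.4g (n = %d)\n", x$m2, x$s2, x$n2))
  invisible(x)
}
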