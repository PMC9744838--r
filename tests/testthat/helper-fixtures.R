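# Shared fixture builders: tiny in-code reports and temp files.

toyEntries <- function(acc, npep = 3, spc = 10, gene = "",
                       cov = 20, len = 300) {
  n <- length(acc)
  data.frame(accession = acc,
             gene = rep_len(gene, n), description = rep_len("", n),
             coverage_pct = rep_len(cov, n),
             n_unique_validated_peptides = rep_len(npep, n),
             spectral_count = rep_len(spc, n),
             nsaf = rep_len(NA_real_, n), length_aa = rep_len(len, n),
             stringsAsFactors = FALSE)
}

toyReport <- function(acc, datasetId = "toy", ...) {
  ProteinReport(toyEntries(acc, ...), datasetId = datasetId)
}

writeReportTSV <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent residue-mass oracle for the mass calculator: plain summation
# over a locally defined standard monoisotopic table
oracleResidueMass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

oracleMass <- function(seq) {
  sum(oracleResidueMass[strsplit(seq, "")[[1]]]) + 18.010565
}

# brute-force digestion oracle: enumerate every substring and keep those
# whose boundaries are consistent with tryptic cleavage and whose internal
# uncut sites are within the allowance
oracleDigest <- function(seq, maxMissed, minLen = 1, maxLen = Inf) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  isCut <- function(i) i >= 1 && i < n && res[i] %in% c("K", "R") &&
    res[i + 1] != "P"
  out <- list()
  for (s in 1:n) for (e in s:n) {
    startOk <- s == 1 || isCut(s - 1)
    endOk <- e == n || isCut(e)
    if (!startOk || !endOk) next
    internal <- sum(vapply(s:(e - 1), isCut, logical(1)))
    if (e == s) internal <- 0L
    len <- e - s + 1
    if (internal <= maxMissed && len >= minLen && len <= maxLen)
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(res[s:e], collapse = ""), start = s, end = e,
        missed_cleavages = internal, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# same substring-consistency contract as oracleDigest but with prefix-sum
# counting of internal cut sites, usable on longer sequences
oracleDigestFast <- function(seq, maxMissed, minLen = 1, maxLen = Inf) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  cutAfter <- res %in% c("K", "R") & c(res[-1], "") != "P"
  cutAfter[n] <- FALSE
  pre <- c(0, cumsum(cutAfter))
  starts <- c(1, which(cutAfter) + 1L)
  ends <- c(which(cutAfter), n)
  out <- list()
  for (s in starts) for (e in ends[ends >= s]) {
    internal <- pre[e] - pre[s]
    len <- e - s + 1
    if (internal <= maxMissed && len >= minLen && len <= maxLen)
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(res[s:e], collapse = ""), start = s, end = e,
        missed_cleavages = internal, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

randomSeq <- function(len) {
  paste(sample(names(oracleResidueMass), len, replace = TRUE),
        collapse = "")
}

# exhaustive hypergeometric upper-tail oracle: enumerate all C(N, n) draws
oracleHyper <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)   # elements 1..K are the set members
  mean(hits >= k)
}
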