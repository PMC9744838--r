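## In-silico tryptic digestion and theoretical monoisotopic mass / m-over-z
## computation with fixed and variable modifications. Constants: proton
## 1.0072765 Da, water 18.010565 Da; residue masses are shipped as an
## editable TSV data file and cached on first use.

WATER_MONO  <- 18.010565
PROTON_MONO <- 1.0072765

.chem_cache <- new.env(parent = emptyenv())

.residueMasses <- function() {
  if (is.null(.chem_cache$residues)) {
    f <- system.file("extdata", "monoisotopic_residue_masses.tsv",
                     package = "proteoFunnel", mustWork = TRUE)
    df <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    .chem_cache$residues <- stats::setNames(df$mass, df$residue)
  }
  .chem_cache$residues
}

#' Standard modification specifications
#'
#' The three modifications used throughout: carbamidomethylation of cysteine
#' (fixed, in-gel digestion), pyridylethylation of cysteine (fixed,
#' in-solution digestion) and methionine oxidation (variable). Loaded from
#' the package's editable modification table.
#'
#' @return data.frame with columns name, target, delta_mass, fixed.
#' @export
standardModifications <- function() {
  if (is.null(.chem_cache$mods)) {
    f <- system.file("extdata", "modifications.tsv",
                     package = "proteoFunnel", mustWork = TRUE)
    .chem_cache$mods <- utils::read.table(f, header = TRUE, sep = "\t",
                                          stringsAsFactors = FALSE)
  }
  .chem_cache$mods
}

#' Create a modification specification
#'
#' @param name modification name.
#' @param target single residue letter, "N-term" or "C-term".
#' @param deltaMass monoisotopic mass shift in Da.
#' @param fixed logical; fixed modifications apply to every matching residue.
#' @return a list of class "ModificationSpec".
#' @export
modificationSpec <- function(name, target, deltaMass, fixed = TRUE) {
  if (!is.finite(deltaMass)) stop("delta mass must be finite")
  ok <- (nchar(target) == 1L && target %in% names(.residueMasses())) ||
    target %in% c("N-term", "C-term")
  if (!ok) stop("target must be a canonical residue letter or a terminus")
  structure(list(name = name, target = target,
                 delta_mass = deltaMass, fixed = fixed),
            class = "ModificationSpec")
}

.namedMod <- function(name) {
  m <- standardModifications()
  row <- m[m$name == name, ]
  if (!nrow(row)) stop("unknown modification: ", name)
  modificationSpec(row$name, row$target, row$delta_mass, row$fixed)
}

.checkCanonical <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% names(.residueMasses()))
  if (length(bad))
    stop("non-canonical residue '", res[bad[1]], "' at position ", bad[1])
  res
}

#' Tryptic in-silico digestion
#'
#' Cleaves after K or R except when the next residue is P (the convention of
#' the common search engines), generating all peptides with 0..maxMissed
#' internal uncut sites. Positions are 1-based inclusive; the length filter
#' is applied last.
#'
#' @param sequence amino-acid sequence (canonical residues).
#' @param maxMissed maximum missed cleavages (default 1).
#' @param minLen,maxLen peptide length bounds (default 1, Inf).
#' @return data.frame with columns peptide, start, end, missed_cleavages,
#'   sorted by (start, end).
#' @export
digestTryptic <- function(sequence, maxMissed = 1L, minLen = 1L,
                          maxLen = Inf) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  if (maxMissed < 0) stop("maxMissed must be >= 0")
  res <- .checkCanonical(sequence)
  n <- length(res)
  ## cut after position i iff residue i is K/R and residue i+1 is not P
  cuts <- which(res %in% c("K", "R") & c(res[-1], "") != "P")
  cuts <- cuts[cuts < n]
  bounds <- c(0L, cuts, n)            # fragment boundaries
  nfrag <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(nfrag)) {
    for (m in 0:min(maxMissed, nfrag - i)) {
      s <- bounds[i] + 1L
      e <- bounds[i + 1L + m]
      out[[length(out) + 1L]] <- c(s, e, m)
    }
  }
  mat <- do.call(rbind, out)
  df <- data.frame(
    peptide = substring(sequence, mat[, 1], mat[, 2]),
    start = mat[, 1], end = mat[, 2], missed_cleavages = mat[, 3],
    stringsAsFactors = FALSE)
  len <- df$end - df$start + 1L
  df <- df[len >= minLen & len <= maxLen, , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Theoretical monoisotopic peptide mass
#'
#' Mass = sum of residue monoisotopic masses + water (18.010565 Da) + sum of
#' modification deltas. Fixed modifications apply to every matching residue;
#' variable modifications only at the stated positions.
#'
#' @param sequence peptide sequence.
#' @param fixedMods character vector of modification names from
#'   \code{\link{standardModifications}} or a list of
#'   \code{\link{modificationSpec}} objects.
#' @param variableMods list of \code{list(position =, mod =)} pairs where
#'   \code{mod} is a name or a ModificationSpec.
#' @return monoisotopic mass in Da.
#' @export
monoisotopicMass <- function(sequence, fixedMods = character(),
                             variableMods = list()) {
  res <- .checkCanonical(sequence)
  masses <- .residueMasses()
  m <- sum(masses[res]) + WATER_MONO
  asSpec <- function(x) if (inherits(x, "ModificationSpec")) x else .namedMod(x)
  for (fm in fixedMods) {
    spec <- asSpec(fm)
    if (spec$target %in% c("N-term", "C-term")) {
      m <- m + spec$delta_mass
    } else {
      m <- m + spec$delta_mass * sum(res == spec$target)
    }
  }
  for (vm in variableMods) {
    spec <- asSpec(vm$mod)
    pos <- vm$position
    if (pos < 1 || pos > length(res))
      stop("modification position ", pos, " outside peptide")
    if (!(spec$target %in% c("N-term", "C-term")) &&
        res[pos] != spec$target)
      stop("modification '", spec$name, "' targets ", spec$target,
           " but position ", pos, " is ", res[pos])
    m <- m + spec$delta_mass
  }
  m
}

#' m/z from monoisotopic mass and charge
#'
#' m/z = (M + z * 1.0072765) / z. Rounding happens only at presentation.
#'
#' @param mass monoisotopic mass in Da (> 0).
#' @param z positive integer charge.
#' @return m/z value.
#' @export
mzFromMass <- function(mass, z) {
  if (any(mass <= 0)) stop("mass must be > 0")
  if (any(z < 1)) stop("charge must be >= 1")
  (mass + z * PROTON_MONO) / z
}

#' Relative mass error in ppm
#'
#' 1e6 * (observed - theoretical) / theoretical. An absent (NA) observed
#' value propagates NA.
#'
#' @param mzObserved observed m/z.
#' @param mzTheoretical theoretical m/z.
#' @return error in ppm.
#' @export
ppmError <- function(mzObserved, mzTheoretical) {
  if (any(mzTheoretical <= 0, na.rm = TRUE))
    stop("theoretical m/z must be positive")
  if (any(!is.na(mzObserved) & mzObserved <= 0))
    stop("observed m/z must be positive")
  1e6 * (mzObserved - mzTheoretical) / mzTheoretical
}

#' Classify peptides as unique or shared across proteins
#'
#' A peptide sequence is unique iff it occurs in exactly one protein's
#' digest.
#'
#' @param peptidesByProtein named list, accession -> character vector of
#'   peptide sequences (digestion already performed).
#' @return data.frame with columns peptide, status ("unique"/"shared"),
#'   accession (the owner for unique peptides, NA for shared).
#' @export
uniquePeptideMap <- function(peptidesByProtein) {
  if (is.null(names(peptidesByProtein)))
    stop("peptidesByProtein must be a named list")
  long <- data.frame(
    accession = rep(names(peptidesByProtein),
                    lengths(peptidesByProtein)),
    peptide = unlist(peptidesByProtein, use.names = FALSE),
    stringsAsFactors = FALSE)
  long <- unique(long)
  n_owners <- table(long$peptide)
  peps <- names(n_owners)
  status <- ifelse(n_owners == 1L, "unique", "shared")
  owner <- rep(NA_character_, length(peps))
  uq <- status == "unique"
  owner[uq] <- long$accession[match(peps[uq], long$peptide)]
  data.frame(peptide = peps, status = as.character(status),
             accession = owner, stringsAsFactors = FALSE, row.names = NULL)
}
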