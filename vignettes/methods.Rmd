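---
title: "Spectral-count protocol comparison and the gene-set funnel: methods"
author: "proteoFunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count protocol comparison and the gene-set funnel: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoFunnel)
```

## The analysis problem

Bottom-up shotgun proteomics of a cultured cell line, run under two
sample-preparation protocols and two exposure conditions with a few
technical repeats each, yields four protein-level identification reports.
The analysis has to answer three questions: does one protocol identify
more proteins (and is the difference significant at these very small
sample sizes); which proteins change abundance under the exposure; and do
the changed proteins concentrate in disease-relevant gene sets. This
package implements that pipeline from the report tables onward — it does
not re-score spectra or re-estimate identification FDR; "validated"
status is trusted from the upstream search platform.

## Quantification model

Within one sample, protein abundance is summarized by the normalized
spectral abundance factor: the spectral count divided by protein length
(SAF), renormalized so the values sum to one. NSAF is compositional by
construction — boosting one protein's share necessarily depresses the
rest — and the package embraces this rather than hiding it: the
normalization invariant (sum equal to 1 within 1e-9) is asserted after
every filtering step that triggers recomputation, and the synthetic
generator samples counts multinomially at fixed depth so the
compositional interaction of spiked fold changes with the background is
present in test data too.

NSAF is recomputed over the post-filter protein universe (after
contaminant removal and the unique-peptide filter) before ratios are
formed. The alternative — carrying the upstream platform's NSAF through
the filters — breaks the unit-sum invariant for the analyzed universe, so
recomputation is the default; the reader functions accept reports with a
pre-computed NSAF column when counts are unavailable, in which case
recomputation is blocked and flagged.

Fold changes are formed only for proteins present in both conditions,
with spectral counts summed over technical repeats per condition before
normalization (summing uses all available evidence and avoids the
small-count instability of per-repeat ratios; proteins seen in only one
condition are reported as presence/absence calls, not ratios). The
selection threshold is a fold change of at least 2 in either direction —
deliberately a threshold rule, not a count-based test, matching the
spectral-counting practice the pipeline reproduces.

## Identification-count statistics

Protocol comparisons use the pooled-variance (Student) two-sample t-test
on per-repeat identification counts, which is also computable directly
from printed summary statistics (mean ± SD, n). The pooled form is the
deliberate choice over Welch: with n of 3 and 4 the Welch degrees of
freedom are unstable, and the pooled statistic is what small-sample
summary comparisons in this literature report. The sample SD convention
is n−1; a guard test confirms that the population-SD convention does not
reproduce the reference statistic (t = 2.95 from 782 ± 337, n = 3 vs
275 ± 92, n = 4). No multiple-testing correction is applied across the
four dataset comparisons, mirroring the analysis being reproduced.

## Peptide chemistry

Tryptic digestion cleaves after K or R except before P — the convention
of the common search engines; peptides with up to a configured number of
missed cleavages are generated, positions 1-based inclusive. Monoisotopic
mass is the residue-mass sum plus water (18.010565 Da) plus modification
deltas; m/z = (M + z·1.0072765)/z. Residue and modification masses ship
as editable TSV data files. Fixed modifications (carbamidomethyl-C for
in-gel digests, pyridylethyl-C for in-solution digests) apply to every
matching residue; Met oxidation is positional.

The package includes a reference panel of nine MCM6 (Q14566) tryptic
peptides with experimentally observed m/z values
(`inst/extdata/mcm6_peptide_panel.tsv`). Six reproduce the calculator's
theoretical m/z at two decimals at the observed charge; three are flagged
non-reproducible in the panel itself: DFYVAFQDLPTR (observed +0.5 at
z = 2, suggesting an unannotated +1 Da variant), ESEDFIVEQYK (a ~7 ppm
discrepancy despite a reported 0 ppm error) and ISNLIVLHLR (inconsistent
with any charge of the unmodified sequence). The package records, and
does not guess, the cause.

## The gene-set funnel and enrichment

Selected proteins are mapped to gene symbols (accession is the join key
throughout; unmapped accessions are listed, never silently dropped), then
intersected sequentially with nested stage sets — disease root, disease
of cellular proliferation, cancer-census skin cancer — and finally tested
for pathway enrichment. Enrichment is a one-sided hypergeometric test
(equivalently the Fisher exact upper tail) with Benjamini–Hochberg
adjustment across the tested sets; the upstream tools this replaces
report only P values without naming statistic or correction, so this is
a deliberate, documented choice. The default universe is the mapped gene
set of the filtered report, i.e. a list-versus-detected-proteome
comparison; the implementation is oracle-tested against exhaustive
enumeration of all draws for every universe size up to 20.

The funnel's published stage counts (dozens of genes per stage) depend on
specific database versions and the full deposited dataset; structure, not
those values, is the contract here, and the shipped GMT fixtures are
synthetic stand-ins with the same nesting.

## qPCR confirmation

ΔΔCt with amplification efficiency fixed at 2 (the classic method).
Multiple reference genes are combined by the arithmetic mean of their
Cts, which at efficiency 2 equals the geometric mean of the linear
quantities; the combination rule is configurable since upstream
publications rarely state it. Follow-up statistics (one-way ANOVA, Tukey
HSD) run on ΔCt values by default — approximately variance-stabilized —
with a fold-scale option. Two invariance properties are tested: a global
Ct shift of one sample cancels in ΔCt, and permuting the reference list
changes nothing.

## What the synthetic generator emulates

The generator reproduces the statistical structure the analysis assumes:

* four datasets (deep protocol 3+3 repeats, shallow 4+5), per-repeat
  depths of 60000 and 15000 validated spectra — the study's replicate
  design and the qualitative deep-versus-shallow contrast;
* 1000 proteins with log-uniform lengths on [60, 3000] aa and
  log-normal(0, 1.2) relative abundances;
* random sequences from a fixed residue-frequency table with K+R ≈ 11%,
  so ≥ 95% of proteins yield at least two unique tryptic peptides of
  7–30 aa (asserted, not assumed) — this is a device for realistic
  peptide yields, not a claim about real proteomes;
* a spiked differential set: one 8× and two 4× up-regulated proteins
  (MCM6/MCM3/MCM7 roles) and a 2×-down trio, placed on upper-mid
  abundance ranks so detection is reliable; a stable housekeeping quartet
  (GAPDH/HPRT/PGK1/TBB5 roles) on abundant ranks; five keratin-like
  contaminants at low abundance;
* a "membrane-like" stratum (20% of proteins) down-weighted 0.3× under
  the shallow protocol, giving the protocol-dependent detection
  efficiency;
* nested gene-set fixtures (disease ⊃ proliferation ⊃ skin cancer ⊃ BIR
  pathway) with the up-spiked genes innermost;
* qPCR plates with true folds 2.8 and 6.1 and technical Ct noise
  SD 0.15 (two biological samples, three technical replicates each).

What it does **not** emulate: peptide-level misidentification and FDR
structure, retention time, isotope envelopes, protein degradation or
shared-peptide inference ambiguity beyond exact sequence duplication,
and biological replicate variance in the proteomics arm (the study
design pools biological material before MS). Passing tests therefore
demonstrate correctness of the computations and calibration of the
fold-change rule under multinomial sampling noise — not robustness to
every failure mode of real LC-MS/MS data.

Generator defaults are the study conditions and are not tuned per test;
two calibration properties are *measured* on the defaults: fewer than 5%
of unspiked proteins pass the fold-change filter (observed ≈ 2%), and the
spiked proteins are recovered within [6, 10] and [3, 5.5] estimated NSAF
fold change and ranked in the top 10 by |log2 fc| in ≥ 95% of 100 seeded
runs.

## Numerical choices and degenerate inputs

* Proton 1.0072765 Da, water 18.010565 Da, standard monoisotopic residue
  table; these reproduce the observed peptide panel at 2 decimals.
* Zero spectral counts keep NSAF 0 and stay in the table; an all-zero
  sample is an error, as is a missing protein length. Protein length
  comes from FASTA when available, else from the report's length column.
* A zero control NSAF excludes the protein from ratios with a warning
  (no ratio can be formed).
* Pooled SD of zero yields t = 0, p = 1 when means agree and an explicit
  degeneracy error otherwise.
* A ppm error of exactly 0 is a plain 0 internally; NA propagates for
  absent observations.
* Enrichment with zero overlap reports p = 1 rather than omitting rows.
* RNG: every stochastic component derives its seed from the single
  user-facing seed (dataset and repeat indices are mixed in modulo
  2^31−18), so runs are byte-identical per seed and repeats are
  independent draws.

## Problem sizes used in the shipped checks

Unit tests run the generator at 200–400 proteins and proportionally
reduced depths, which exercises the same code paths at a second or less
per case; the acceptance checks (NSAF normalization sweep, 100-run
recovery, null calibration, end-to-end determinism) run at the full
default scale of 1000 proteins and 60000/15000 spectra, about two
minutes in total. These sizes are the package's own trade-off between
statistical resolution and a test suite that stays fast enough to run
habitually.

## Known limitations

* The pipeline starts from protein-level report tables; peptide-to-
  protein inference and FDR control are upstream concerns.
* Fold-change thresholding has no per-protein error model; the null
  calibration quantifies, but does not remove, its false-positive rate
  at low counts.
* The hypergeometric universe choice materially affects enrichment P
  values; the default (detected proteome) is one defensible choice among
  several, and alternatives are a one-line configuration change.
* Spreadsheet report exports must be saved as delimited text before
  ingestion; the readers deliberately consume only diffable text
  formats.
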