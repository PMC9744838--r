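Package: proteoFunnel
Title: Label-Free Spectral-Count Proteomics Comparison and Gene-Set Funnel
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of label-free shotgun proteomics
    identification reports across sample-preparation protocols and exposure
    conditions. Implements normalized spectral abundance factor (NSAF)
    quantification, validation filters (minimum unique validated peptides,
    keratin contaminant screening), multi-set Venn partitioning and
    pooled-variance t-tests on identification counts, NSAF fold-change
    selection feeding a staged gene-set funnel (disease ontology, cancer
    census, pathway) with exact hypergeometric enrichment, in-silico tryptic
    digestion with monoisotopic mass and m/z computation under fixed and
    variable modifications, and delta-delta-Ct qPCR relative expression with
    ANOVA and Tukey HSD follow-up. A synthetic-data generator produces
    complete ground-truthed inputs (spectral-count reports, FASTA, gene-set
    GMT fixtures, contaminant lists, Ct plates) so every stage is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
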