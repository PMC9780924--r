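Package: famforge
Title: Gene-Family Discovery, Evolution and Expression Screening Toolkit
Version: 0.1.0
Authors@R: person("famforge", "developers", role = c("aut", "cre"),
    email = "famforge@example.org")
Description: Reusable pipeline for genome-wide identification and
    characterization of protein gene families such as the plant F-box
    superfamily. Implements seed-profile scanning of a proteome with
    PSI-BLAST-style iterative PSSM expansion, CD-HIT-style greedy identity
    clustering, progressive multiple alignment with conserved-site
    statistics, C-terminal domain-architecture annotation, duplicate-gene
    detection with tandem/dispersed classification and Nei-Gojobori (1986)
    Ka/Ks selection analysis, reciprocal-best-hit ortholog pairing,
    median-of-ratios expression normalization with complete-linkage
    hierarchical clustering, 2^-ddCt quantification, and disease-index
    phenotype scoring. Ships truth-tagged synthetic data generators
    (proteomes with planted domain families, duplicate pairs evolved at a
    known dN/dS, negative-binomial count matrices, disease-grade tables)
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
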