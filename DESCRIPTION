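Package: SNBPscan
Title: Identification and Characterization of Sperm Nuclear Basic Protein Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for the computational discovery of sperm nuclear basic
    protein (SNBP) candidates from tissue-resolved transcriptomes and protein
    sequences, modelled on the biology of hymenopteran insects. Identifies
    genes expressed exclusively in the male reproductive tract by RPKM
    thresholds, computes protein basicity and architecture features
    (isoelectric point from configurable pKa tables, amino-acid composition,
    arginine placement, arginine/lysine-rich window detection), applies gene
    ontology triage and SNBP-class decision rules (protamine, protamine-like,
    testis-specific histone, HMG-box), estimates dN/dS (omega) overall and for
    restricted regions by Nei-Gojobori (1986) counting and by a pairwise
    one-ratio Goldman-Yang codon model, and summarizes brood sex ratios with
    one-way ANOVA and Tukey HSD. Includes truth-labelled synthetic-data
    generators so every stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
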