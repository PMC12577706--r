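Package: editrisk
Title: Predicting CRISPR-Cas9 Editing Outcomes and Structural-Variant
    Hotspots from Genomic Repetitiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the editability of a genome with CRISPR-Cas9.
    Computes local and global sequence-repetitiveness indices from
    shortest-unique-substring lengths, tandem-repeat arm homology, and
    genomic-context features at NGG PAM sites; labels per-clone editing
    outcomes from variant observations (edit-distance intent classification,
    rank-of-rank copy-number-loss detection, breakpoint homology, bulk
    coverage-drop quantification); trains gradient-boosted submodels for
    unedited, deletion, translocation and structural-variant outcomes with
    imbalance-aware resampling and repeated cross-validation; and derives
    genome maps of difficult-to-edit regions, SV hotspots, and
    loxP-distance/breakpoint-colocalization summaries. A simulation module
    generates genomes with planted repeat structure, outcome labels from a
    stated generative rule, and binned coverage with planted copy losses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    xgboost,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
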