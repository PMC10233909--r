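Package: phycoPUL
Title: Phycosphere Community Profiling and Polysaccharide Utilization
    Locus Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for desk-scale analysis of macroalgal phycosphere
    microbiomes. Classifies core, dominant and host-specific genera from
    16S rRNA relative-abundance tables by prevalence and abundance
    thresholds; detects candidate polysaccharide-degradation loci in
    annotated bacterial genomes with a gene-count sliding window and
    types their susCD architecture; clusters polysaccharide utilization
    loci (PULs) by ordered CAZyme-family composition and infers candidate
    substrates from a configurable rule table; tiers genome quality,
    dereplicates genomes from average nucleotide identity (ANI) matrices
    and reconciles multi-source taxonomies; and ships synthetic-data
    generators with planted ground truth so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    igraph,
    rtracklayer,
    GenomicRanges,
    vegan,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
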