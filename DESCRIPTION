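Package: rgdtools
Title: Rare Genetic Disorder Catalog Matching, Symptom-Based Prediction and
    Gene Variant-Density Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for analysing rare genetic disorders (RGDs) against
    plain-text catalogs, without any hosted database. Matches cohort VCF
    variants against a ClinVar-like pathogenic-variant catalog and classifies
    each as identical (exact chromosome, position and allele match) or similar
    (same site, different alleles), stratified by clinical significance and
    Mendelian inheritance mode; ranks candidate disorders from selected
    clinical symptoms using frequency-term weights; profiles pathogenic
    variant density along a gene in consecutive fixed-width (default 500 bp)
    segments with a four-tier chromosome/gene/exon/variant track model; and
    generates deterministic synthetic catalogs, symptom tables, gene models
    and cohort VCFs with planted, machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
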