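Package: sexRAD
Title: Coverage- and Missingness-Based Sex Assignment from RAD-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns sex to individuals from reduced-representation
    sequencing (RAD-seq/GBS) data mapped to a chromosome-level reference
    genome carrying assembled sex chromosomes. From an all-sites VCF (fixed
    and variable positions within RAD loci, with per-genotype depth) the
    package accumulates per-individual missingness and mean coverage depth
    stratified by chromosome class (autosomal, X-like, Y-like), computes two
    sexing indexes - Index X, the ratio of X to autosomal mean depth, and
    Index Y, the relative completeness deficit of the Y versus the X - and
    calls the homogametic or heterogametic sex per individual with
    confidence flags. Includes locus-level retention filters
    (minimum locus-sharing proportion, maximum observed heterozygosity), a
    synthetic all-sites-VCF cohort simulator with known truth for offline
    validation, dispersion plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
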