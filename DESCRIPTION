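Package: msatgbs
Title: Microsatellite Genotyping by Sequencing with Combinatorial Barcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for amplicon-based microsatellite genotyping by
    sequencing (GBS) with individual combinatorial dual barcoding.
    Builds and validates barcode schemes, hierarchically sorts paired
    amplicon reads into the five standard recovery categories, calls
    diploid length alleles from read-length histograms with stutter
    filtering, and provides the downstream population-genetic layer:
    completeness filtering, Hardy-Weinberg exact tests, sequential
    Bonferroni correction, observed and unbiased expected
    heterozygosity, rarefied allelic richness, Weir-Cockerham FST with
    locus bootstrap and permutation tests, Nei's DA distances,
    drift-based statistical power simulation, locus-saturation curves
    and temporal high-grading of marker panels.  A built-in simulator
    renders drift-structured multi-population truth as barcoded paired
    FASTQ with PCR stutter, substitution error and barcode loss, with
    complete truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    generics,
    ggplot2,
    yaml,
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
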