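Package: autozyg
Title: Pedigree and Genomic Inbreeding from Runs of Homozygosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing pedigree-based and genomic inbreeding in
    livestock populations. Computes Wright's pedigree inbreeding coefficient
    (F_PED) by an exact tabular recursion, detects runs of homozygosity (ROH)
    with a sliding-window caller under configurable threshold settings,
    derives the genomic inbreeding coefficient F_ROH, compares estimators
    across a threshold grid (Pearson correlations, paired t-tests), finds
    population-consensus ROH regions by a sweep-line over segment endpoints,
    and intersects them with quantitative trait locus (QTL) interval tables.
    A gene-dropping simulator with recombination provides pedigrees,
    two-panel SNP genotypes and ground-truth autozygosity for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
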