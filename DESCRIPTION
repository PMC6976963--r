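Package: poolcross
Title: Resistance Allele Mapping from Genetic Crosses and Pooled Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Untangles insecticide-resistance alleles in multi-resistant mosquito
    populations from pooled targeted DNA-seq of a controlled cross / dose-segregation
    design. Provides a forward simulator of the cross and selection experiment with a
    probit tolerance model, copy-number detection from capture exon coverage
    (library-size normalization, common-reference ratios, centre-reduced per-gene
    profiles and a per-line pass rule), allele-frequency trajectory filtering with
    initial-frequency bands, a Bayesian F_ST outlier scan with reversible-jump MCMC
    and q-values, and a dual-evidence integration step producing selection regions,
    Venn overlaps and nonsynonymous hit tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
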