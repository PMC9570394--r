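Package: sexlinkr
Title: Sex-Linked Marker Discovery and Sex-Chromosome Evolution from
    Reduced-Representation Genotype Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens multi-individual GBS/RAD-seq locus catalogs for
    sex-linked SNPs and sex-limited tags under both XY and ZW expectations,
    validates candidates in silico against sex-partitioned read pools, calls
    the heterogametic system per species with an exact binomial test, assigns
    confirmed markers to chromosomes of a third-party reference genome by
    direct and two-step indirect mapping with E-value and best-hit-gap rules,
    tests for chromosomal concentration, classifies multispecies gene trees
    (in-house neighbor-joining on Kimura two-parameter distances with
    bootstrap) as gametolog-clustered versus species-clustered evidence for
    X-Y recombination, and counts sex-chromosome turnovers and heterogamety
    shifts on a fixed species phylogeny by small parsimony. A seeded
    synthetic-data generator emulates multi-species catalogs with planted
    sex-linked loci so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
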