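Package: elimrep
Title: Discovery and Chromosomal Mapping of Germline-Restricted Tandem Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying programmed DNA elimination in hagfish-like
    genomes in which a set of germline-restricted (eliminated) chromosomes is
    discarded from somatic cells. Implements discovery of germline-enriched
    satellite families by differential canonical k-mer counting between
    germline and somatic read sets, greedy unitig assembly of enriched k-mers
    and tandem monomer inference (smallest period, strand/rotation-canonical
    monomer), characterization of repeat monomers from cloned copies (star
    alignment, majority consensus, gap-excluded pairwise divergence, GC
    content, direct repeats, ORF scan), in-silico PCR ladder prediction on
    tandem arrays, and classification of multi-probe chromosome intensity
    profiles into co-localization groups, symmetric karyogram patterns and
    fiber-level interspersion. A seeded synthetic-data generator produces
    germline/somatic genomes, reads, clone sets and probe profiles with a
    ground-truth manifest for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
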