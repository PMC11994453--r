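Package: dsbscan
Title: Nomination and Scission Profiling of Cas9 Double-Strand Breaks from
    Read-End Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses unique-molecule read-end pileups from double-strand-break
    (DSB) capture sequencing of CRISPR-Cas9 digested genomic DNA. Provides a
    guided search that nominates on-target and off-target cleavage sites for a
    set of guide RNAs with Poisson enrichment testing against a non-target
    control, quantifies the scission profile of each site (blunt versus
    staggered ends and 5' overhang lengths) from the strand-resolved geometry
    of break-proximal read ends, trains gradient-boosted regression models
    that predict the blunt rate of a target from its protospacer sequence,
    scores allele-specific blunt-rate changes at SNVs falling in protospacer
    positions 17 or 18, and triages pathogenic single-nucleotide deletions
    that a staggered cut followed by a templated +1 insertion could revert.
    Includes a fully parameterised synthetic-data generator that emulates the
    end-capture chemistry (UMIs, PCR duplicates, end-repaired overhang
    footprints, uniform background) for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    xgboost
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
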