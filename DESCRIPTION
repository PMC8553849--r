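Package: bamscrub
Title: Genotype Removal from Aligned Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rewrites every aligned read in a BAM file so that its sequence is
    pure reference genome sequence at its aligned location, eliminating donor
    SNPs, indels and clipped variant sequence while preserving 5' mapping
    positions, splice junctions and non-genetic metadata (cell barcodes, UMIs,
    read groups, custom tags). Includes a seeded synthetic fixture generator
    (reference, donor haplotype with planted variants, aligner-faithful reads)
    and an independent pileup-based auditor that verifies zero non-reference
    positions survive sanitization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    Rsamtools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
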