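Package: capsmark
Title: Bulk PCR-Based Marker Design from Sequence Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts next-generation sequencing variant calls (VCF or Roche
    gsMapper 454HCDiffs dialect) into GFF3/GVF variant features, detects
    restriction-site (CAPS) polymorphisms against a panel of enzymes with
    IUPAC-degenerate recognition sites, designs variant-masked flanking
    primer pairs for CAPS, indel and high-resolution melting (HRM) assays
    under marker-specific amplicon-size constraints, and validates primer
    sets by in-silico PCR. Includes a seeded synthetic fixture generator
    with digest-verified ground truth and an end-to-end workflow runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    tidyr,
    ggplot2,
    generics,
    withr,
    utils,
    stats,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
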