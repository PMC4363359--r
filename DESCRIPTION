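Package: poolscreen
Title: Pooled-Amplicon Mutation Screens: Design, Simulation, Calling and
    Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for TILLING-by-sequencing screens that pool a
    mutagenized population in three dimensions (plate, column, row) and
    sequence barcoded amplicons on an Ion-Torrent-like instrument. Provides
    the tridimensional pooling design and its inversion (deconvolution of
    flagged pool sets back to source individuals), template-dilution
    arithmetic, primer and barcode utilities, a synthetic screen simulator
    with an empirical substitution/homopolymer error model, FASTQ
    demultiplexing, primer trimming and semi-global amplicon alignment,
    and a rare-variant caller that flags outlier pools by a standard
    deviation band and reports confidence-tiered candidate mutations.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
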