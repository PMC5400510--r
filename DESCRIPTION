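Package: dyadkit
Title: Nucleosome Dyad Positioning from MNase-Seq Fragments on Origin Templates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nucleosome-positioning analysis of paired-end MNase-seq
    libraries from short DNA templates carrying a replication origin.
    Implements fragment-length size selection, dyad-proxy midpoint extraction,
    Gaussian-kernel dyad-density tracks normalized to read depth, consensus
    dyad peak calling with minimum-separation suppression, ACS-relative
    coordinate handling, cross-condition peak pairing and dyad-shift
    measurement, percent-of-reference replicate quantification, and a
    seeded synthetic MNase-fragment generator emulating remodeler-defined
    nucleosome landscapes (nucleosome-free region plus positioned flanking
    dyads) so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
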