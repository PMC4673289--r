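Package: sirnakit
Title: Design and Validation of siRNAs with Minimized Off-Target Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing small interfering RNAs (siRNAs) with
    minimized off-target potential and for analysing the paired
    Match/Mismatch assays used to validate them. Enumerates 19-nt guide
    candidates on a target transcript while avoiding the 3'UTR, screens
    guides against a transcriptome for long complementary runs and
    seed-complement frequency, constructs single-substitution Mismatch
    negative controls and degenerate sN/dN guide pools, quantifies
    knockdown from qPCR Ct tables by the 2^-ddCt method, and classifies
    genes as essential or off-target-confounded from paired knockdown and
    cell-viability measurements. Includes seeded synthetic-fixture
    generators producing transcriptomes with planted off-target sites and
    assay tables with planted effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
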