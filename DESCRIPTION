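Package: crisprterm
Title: Rho Termination and BoxA Antitermination Analysis of Bacterial
    CRISPR Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying premature Rho-dependent termination of
    bacterial CRISPR array transcription and its rescue by BoxA/Nus-factor
    antitermination. Implements spacer-to-ChIP-peak assignment via Cascade
    seed and PAM matching, peak-center occupancy normalization with
    deletion-ratio assignment refinement, per-protospacer interference
    quantification from pooled conjugation sequencing, cas2-flank
    extraction and trimming for boxA motif screens, and a ZOOPS
    expectation-maximization motif finder. A synthetic-data generator
    emulates termination along CRISPR arrays so every stage can be
    exercised and validated against planted ground truth without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
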