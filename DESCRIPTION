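Package: dhprof
Title: Comparative Sequence-Structure Profiling of Polyketide Synthase
    Dehydratase Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of dehydratase (DH) domains from
    modular type I polyketide synthases: coordinate-file parsing with
    missing-residue bookkeeping, sequence-guided iterative Kabsch C-alpha
    superposition with outlier rejection, per-residue B-factor flexibility
    profiling, occupancy-refined per-column Shannon entropy over a multiple
    sequence alignment mapped onto a reference structure, conserved-motif and
    His/Asp catalytic-dyad geometry, and an integrative caller for variable
    substrate-binding loop regions. Includes deterministic synthetic-data
    generators (toy structures with planted transforms, B-factor profiles and
    unmodeled gaps; alignments with controlled column compositions) so the
    full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
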