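Package: regulonscan
Title: Comparative Reconstruction of Bacterial Transcription-Factor Regulons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs bacterial transcription-factor regulons across related
    genomes: phylogenetic footprinting of orthologous upstream regions, position
    weight matrix (PWM) construction with palindrome symmetrization, genome-wide
    scanning with per-genome threshold calibration against a bounded fraction of
    hit genes, rescue of weak sites supported by orthologous positional
    conservation, operon inference from same-strand intergenic distances,
    cross-genome regulon assembly and operon extension, and motif-geometry
    analyses (palindrome verification, half-site spacer enumeration, LysR-box
    detection, helical-turn phasing). Includes a synthetic multi-genome
    generator with planted regulons and full ground truth for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
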