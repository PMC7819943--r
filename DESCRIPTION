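Package: pbmotif
Title: Promoter-Tiling Protein-Binding Microarray Design and Motif Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing promoter-tiling protein-binding microarrays
    (overlapping fixed-length probes spanning upstream regulatory regions) and
    for inferring transcription-factor DNA-binding motifs from probe
    fluorescence intensities. Implements two-segment rank-intensity regression
    to derive a strong-binding cutoff, k-mer decomposition with
    pseudo-intensity averaging, G/C homopolymer-run filtering, seed-template
    motif clustering with position weight matrix construction, per-position
    mutation-effect profiling and greedy motif extension, rank-based
    (Wilcoxon-Mann-Whitney) motif enrichment statistics, promoter and probe
    scanning for putative target genes, and a seeded synthetic PBM simulator
    with planted motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
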