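Package: secrc
Title: Super-Enhancer Calling and Core Regulatory Circuitry Analysis from
    H3K27ac ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies super-enhancers (SEs) from H3K27ac ChIP-seq peak
    calls and fragment tracks using ROSE-style stitching and the slope-1
    tangent cutoff on the ranked signal curve, merges SE calls across cell
    lines and tumor types to classify conservative versus tumor-specific
    SE-regulated genes and transcription factors, scans nucleosome-free
    regions for known TF motifs with log-odds position weight matrix
    scoring and hypergeometric enrichment, and derives the core regulatory
    circuitry of autoregulated, mutually binding transcription factors as
    fully interconnected cliques. Ships a deterministic synthetic-data
    generator with planted ground truth so every stage of the pipeline can
    be validated end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
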