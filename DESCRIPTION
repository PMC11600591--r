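Package: cnedegen
Title: Detection of Degenerated Conserved Noncoding Elements in Limbless Tetrapods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale comparative-genomics pipeline for studying convergent
    limb loss through regulatory sequence decay. Detects degenerated conserved
    noncoding elements (dCNEs) in limbless tetrapod lineages by sliding-window
    identity scans against parsimony-reconstructed ancestral sequences,
    classifies convergence across lineages and estimates per-species
    degeneration rates, contrasts observed identity with GTR neutral
    simulations at matched timescales, performs Fisher and hypergeometric
    enrichment tests with BH FDR control, screens orthologs for limited intron
    expansion with a Monte Carlo overlap test, and annotates elements with
    enhancer activity, pleiotropy, evolutionary origin, and convergent
    amino-acid sites. A synthetic-data module generates trees, alignments with
    known ancestors and planted degeneration, and feature fixtures with ground
    truth, so the whole pipeline runs and is validated without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
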