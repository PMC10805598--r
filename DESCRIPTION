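Package: pssver
Title: Position-Specific Stationary Vectors for Transcription Factor
    Binding Site Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers position-specific stationary vectors (PSSVs) for
    transcription factor binding sites from gapless orthologous sequence
    across species. Implements the F81 and HKY85 nucleotide substitution
    models, Felsenstein's pruning algorithm, and a fast sum-of-stars
    likelihood evaluator for F81 on moderate-sized trees; maximum-likelihood
    fitting of branch proximities on neutral positions and of per-position
    stationary vectors within motifs; marginal ancestral nucleotide
    posteriors at the root and conditional PSSVs for detecting positional
    coupling; position weight matrix construction, column scrambling,
    information content and Jensen-Shannon divergence utilities; and a
    simulator of binding-site evolution along a tree used to validate every
    inference step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
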