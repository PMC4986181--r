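Package: sdtnet
Title: Signed Drug-Target Network Analysis and Drug-Pair Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed bipartite drug-target networks from edge lists in
    which each drug action carries a mode-of-action label (agonist, inhibitor,
    blocker, ...) mapped to a positive or negative sign. Quantifies coherent
    versus incoherent joint actions of drug pairs on shared targets, tests
    per-pair enrichment with a cumulative binomial against the network-wide
    coherence probability, compares observed overlap statistics with a
    degree- and sign-preserving null model, classifies length-4 cycles into
    coherent, mixed and incoherent sign patterns, and computes synergistic
    and side-effect score coefficients to screen drug pairs for mutual
    pharmacological benefit and side-effect mitigation. Includes a synthetic
    network generator with heavy-tailed degrees and controllable per-drug
    sign monochromaticity, plus deterministic worked-example fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
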