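Package: rabscan
Title: Profile-Based Classification and Conservation Analysis of Rab-Like
    Small GTPases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for detecting and characterising Rab-like small
    GTPases in proteomes: position-specific profile models built from
    multiple sequence alignments, a three-stage classifier (G-domain
    detection, RAS-superfamily family assignment, Rab subfamily
    assignment) with RabF motif scanning, plurality-rule consensus and
    per-column Shannon entropy, affine-gap global and local pairwise
    alignment, C-terminal prenylation-motif and polybasic-region
    analysis, and Kabsch least-squares superposition of C-alpha
    coordinates. Includes a synthetic sequence-family generator with
    planted motifs and ground truth so the full pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
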