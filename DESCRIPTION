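Package: tandclust
Title: Variable-Mode Clustering of Dichotomous Neuropsychiatric Checklist Items
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for discovering natural clusters among
    binary (yes/no) neuropsychiatric checklist items. Computes mean squared
    contingency (phi-squared) association matrices with pairwise deletion,
    clusters the items (not the subjects) with agglomerative linkages (Ward,
    complete, average, McQuitty), divisive DIANA and fuzzy FANNY, assesses
    cluster robustness by bootstrap co-clustering proportions at fixed k,
    runs exploratory factor analysis (principal components and principal axis
    extraction with varimax, quartimax, promax, oblimin and cluster-target
    rotations), matches factor solutions to cluster solutions via Tucker
    congruence with Orthogonal Procrustes alignment, scores internal
    consistency with Cronbach's alpha (KR-20 for binary items), and integrates
    the evidence into a final named-cluster table with an explicit, auditable
    reassignment rule. Includes a latent-threshold simulator of correlated
    binary data with planted block structure so the full pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
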