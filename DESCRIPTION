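Package: facematchr
Title: Leave-One-Out Face-Matching Evaluation for Syndromic Intellectual
    Disability
Version: 0.1.0
Authors@R:
    person("facematchr", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Evaluation pipeline for computer face-matching of individuals
    with syndromic forms of intellectual disability. Provides a labelled
    image/embedding database ("facebase") data model with CSV I/O, seeded
    synthetic generators for clustered face embeddings, parametric face
    sketches and clinician ratings, a low-resolution DCT baseline face
    descriptor, leave-one-out top-k same-syndrome retrieval with
    same-individual exclusion, an exact hypergeometric-tail and Monte Carlo
    random-ranking null model for expected match counts, Yates-corrected
    chi-square goodness-of-fit statistics, and software-versus-clinician
    concordance (paired 2x2 tables, McNemar's test, Cohen's kappa), together
    with report rendering and verification against published summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
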