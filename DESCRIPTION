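Package: kinens
Title: Kinetic Ensemble Analysis of Homonuclear NOE Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes homonuclear NOE observables exactly from a structural
    ensemble equipped with a transition-rate matrix over its members.
    Correlation functions and spectral densities are obtained analytically
    from the spectral decomposition of the rate matrix and pairwise
    dipole-dipole interaction tensors, methyl and aromatic ring rotations
    are folded in via Kronecker sums, and NOESY buildup curves follow from
    the Solomon relaxation matrix.  Includes goodness-of-fit scoring with
    the uncentered correlation, gradient-based optimization of motional
    timescales, greedy subensemble selection, and generators for the
    planar two-timescale and two-distance toy systems used to validate
    the approach against extended model-free theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
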