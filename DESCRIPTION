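Package: cvmlattice
Title: Cluster Variation Method for Bistate Zigzag Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Statistical thermodynamics of binary (on/off) activation
    patterns on one-dimensional zigzag chains and two-dimensional staggered
    grids using the cluster variation method (CVM). Counts configuration
    variables (single units, nearest-neighbor pairs, next-nearest-neighbor
    pairs, and triplets) under periodic wraparound conventions, evaluates
    the CVM free energy whose entropy goes beyond the mean-field
    single-unit form, computes equilibrium configuration variables as
    closed forms in the interaction-enthalpy parameter h for the
    equiprobable case, and inverts observed triplet fractions to estimate
    h for a given pattern. Includes seeded generators for reference
    ferromagnetic-like, equilibrium-motif, antiferromagnetic-like, and
    random patterns, and a command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
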