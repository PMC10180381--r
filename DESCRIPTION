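Package: d4tune
Title: System-Specific Tuning of Semi-Classical Dispersion Corrections for
    Water Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for fine-tuning the empirical scaling factors of
    semi-classical (Grimme-style) two-body dispersion corrections to density
    functional theory against benchmark interaction energies of molecular
    water clusters. Reads cluster geometries in XYZ format, evaluates the
    pairwise C6/r^6 + C8/r^8 dispersion energy with rational (Becke-Johnson)
    damping, assembles one-body-subtracted interaction-energy deviations
    against a benchmark method, and optimizes the S6/S8 scaling factors by
    exact piecewise-linear (breakpoint) minimization of the mean absolute
    deviation across clusters of growing size. Includes a synthetic water
    cluster and mock energy table generator with known ground-truth scaling
    factors, deviation statistics (Err, MSE, MAE, MAE per molecule), and a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
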