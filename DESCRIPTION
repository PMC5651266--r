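Package: foursphere
Title: Analytical Four-Sphere Head Model for EEG Forward Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes scalp and within-head electric potentials generated by
    current dipoles in a four-layer concentric-sphere volume conductor (brain,
    cerebrospinal fluid, skull, scalp), using the corrected Legendre-series
    solution of the quasi-static Poisson equation with potential- and
    current-continuity boundary conditions. Provides an independent
    per-harmonic linear-system solver derived directly from the boundary
    conditions, closed-form reference solutions (homogeneous single sphere,
    infinite homogeneous medium), an executable validation suite enforcing the
    model's physical limits, scalp-map gridding, electrode-file input/output
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
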