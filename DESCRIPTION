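Package: srca
Title: Spherical Rotation Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nonlinear dimension reduction onto low-dimensional spheres by
    direct minimization of a geometric point-to-sphere loss. After a
    data-driven orthogonal rotation (PCA by default, orthomax family or ICA
    optionally), the method selects the coordinate subset carrying the
    spherical structure (exhaustive search or an l1 relaxation), estimates
    the sphere centre and radius by alternating closed-form radius updates
    with gradient descent on the centre, and projects the data back onto the
    fitted sphere in the original frame. Includes PCA and spherical-PCA
    baselines, coranking-matrix embedding-quality scores, cluster-separation
    scores, seeded synthetic generators (sub-spheres, tori, planes,
    cell-cycle-like cyclic data), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
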