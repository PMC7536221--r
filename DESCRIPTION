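Package: cineflow
Title: Motion-Corrected 4D Flow Cine MRI Velocity Reconstruction from
    Multi-Planar Phase Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-component, optionally cardiac-phase-resolved
    velocity vector fields from multiple non-coplanar stacks of
    velocity-sensitive bSSFP phase images, as acquired for fetal whole-heart
    flow imaging. Implements the velocity-to-phase encoding model with
    gradient-first-moment reorientation under rigid motion, third-order
    polynomial background phase correction, regularized conjugate-gradient
    inversion of scattered multi-stack phase samples, post-reconstruction
    velocity drift correction, and ROI-based flow quantification. Includes a
    digital six-pipe flow phantom simulator used for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
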