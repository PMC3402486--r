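Package: oftmech
Title: Biomechanics of the Embryonic Heart Outflow Tract from 4D Optical
    Coherence Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies biomechanical stimuli in the tubular embryonic heart
    outflow tract from 4D optical coherence tomography (OCT) image sequences:
    cycle synchronization of unsynchronized per-plane acquisitions,
    active-contour segmentation of the myocardial and endocardial boundaries,
    wall kinematics (circumferential strain, area shortening fraction, radial
    velocity, closure timing), Doppler-phase velocimetry with temporal phase
    unwrapping and angle correction, Laplace-law myocardial wall stress, and a
    reduced-order quasi-steady model of pulsatile flow and wall shear stress in
    a moving, tapered, elliptical lumen. A parametric digital phantom of the
    peristaltic outflow tract, with speckled intensity and wrapped Doppler
    phase channels and known ground truth, drives verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
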