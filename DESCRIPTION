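Package: fibroslab
Title: Multi-Layer 3D Atrial Slab Simulation of Intramural Fibrosis and
    Endo-Epicardial Dissociation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds stochastic seven-layer atrial slab microstructures with
    controlled intramural fibrosis degree (IFD) and endo-epicardial
    dissociation degree (EDD), solves the monodomain reaction-diffusion
    equation with Nygren human atrial myocytes electrotonically loaded by
    gap-junction-coupled active fibroblasts, initiates spiral waves with an
    S1-S2 endocardial protocol, and quantifies the resulting wave dynamics:
    phase fields and phase-singularity tracking, unipolar and bipolar
    electrograms and pseudo-ECG, endo-epicardial breakthrough and intramural
    re-entry detection, and group-level stability statistics
    (Kaplan-Meier curves, Kolmogorov-Smirnov and t tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    survival,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
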