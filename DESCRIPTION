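Package: lvhelix
Title: Helix-Angle Fiber Architecture and Biomechanics of the Fetal Left Ventricle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulation and analysis of fetal left-ventricular
    (LV) myocardial mechanics as a function of the transmural helix-angle
    fiber architecture. Generates idealized half-prolate LV geometries as
    quadratic tetrahedral meshes, assigns rule-based linearly varying
    helix-angle fiber fields parameterized by the transmural mean angle and
    the epicardial-to-endocardial angle difference, and simulates cardiac
    cycles with a Fung-type transversely isotropic passive law and a
    calcium-activation active-tension model. Cycles are driven either by a
    prescribed smoothed volume-over-time waveform or by coupling to a
    closed-loop lumped-parameter model of the fetal circulation. Biomechanics
    metrics (stroke work, volume-averaged myofiber stress, deformational
    strain-energy burden, transmural strain variance, global strains) are
    swept over grids of helix-angle configurations to build interpolated
    optimality maps, compare simulation approaches by structural similarity,
    and match simulated strains against image-derived strains.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
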