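Package: filmdeg
Title: Reaction-Diffusion Modelling of Enzymatic Degradation of
    Semicrystalline Polymer Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the enzymatic degradation of thin semicrystalline
    polyester films with a one-dimensional two-state (crystalline/amorphous)
    reaction-diffusion model. Free enzyme diffuses through the film with a
    porosity-dependent effective diffusivity, binds reversibly to crystalline
    and amorphous polymer, converts crystalline to amorphous material
    (amorphisation), and hydrolyses both phases to soluble products. Provides
    stiff method-of-lines integration of the model, weight-loss and
    crystallinity observables, joint weighted least-squares calibration
    against degradation datasets, Bayesian uncertainty quantification by
    differential-evolution MCMC with snooker updates, time-dependent Sobol
    sensitivity analysis, and predictive film-thickness sweeps with
    Damkohler-number regime classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
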