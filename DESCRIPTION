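Package: radonclear
Title: Deposition, Mucociliary Clearance and Decay of Inhaled Radon Progeny in Bronchial Airways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled modelling of the deposition, mucociliary clearance and
    radioactive decay of the short-lived radon progenies (Po-218, Pb-214,
    Bi-214/Po-214) in a central human airway bifurcation. Provides closed-form
    and stochastic Bateman decay-chain solvers, a deterministic typical-path
    whole-lung deposition cascade with analytic diffusion, sedimentation and
    impaction mechanisms, a generation-wise mucociliary escalator with decay
    in-growth, a parametric surrogate of the bifurcation wall surface with an
    inhomogeneous deposition-site sampler and a flux-conserving mucus velocity
    field including a slow carinal zone, an event-driven dynamic simulation of
    deposition, clearance and alpha decay, alpha-track microdosimetry with
    ellipsoidal epithelial cell nuclei, and exponential cell-death and
    cell-transformation dose responses. Results are returned as tibbles with
    tidy() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
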