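Package: clotsim
Title: In Silico Histotripsy Ablation and Catheter-Directed Thrombolysis
    of Venous Thrombus
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Serial simulation pipeline coupling a Monte Carlo model of
    histotripsy bubble ablation in heterogeneous venous thrombus to an
    explicit finite-difference solution of the perfusion-diffusion
    equation for catheter-infused thrombolytic (rt-PA), and closed-form
    fibrinolysis kinetics.  Synthetic histology sections with controllable
    fibrin/red-blood-cell composition stand in for annotated H&E sections,
    a parametric elliptical-Gaussian focal field models the 1.5-MHz
    focused source, and an analytic Kelvin-Voigt maximum-radius model
    sizes the bubbles.  Dose-response outputs (ablation area, hemoglobin
    release, fibrin degradation products) are summarised with one-way
    ANOVA/Tukey HSD, Pearson correlation, and a z-scored linear
    regression coefficient linking hemolysis to fibrinolysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
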