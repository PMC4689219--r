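Package: fateswitch
Title: Bistable Toggle-Switch Dynamics of the Epiblast Versus Primitive
    Endoderm Fate Decision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation and analysis of a mutual-repression
    NANOG/GATA gene-regulatory switch driven by a pulsed, heterogeneous
    exogenous GATA input and modulated by FGF/MAPK signaling. Provides
    phase-plane tools (nullclines, equilibria, separatrix, basins,
    path-integral quasi-potential landscapes), heterogeneous population
    simulation through pulse-chase protocols with attractor-based fate
    calling, and single-cell analytics: per-timepoint ROC/AUC fate
    prediction with bootstrap uncertainty, optimal Youden thresholds,
    hierarchical trace clustering, and smoothed-histogram peak detection
    for flow-cytometry-like intensity samples. A synthetic-data module
    generates noisy time-lapse traces and snapshot intensity samples so
    the full analysis stack can be exercised without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
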