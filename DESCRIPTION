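Package: cdkclock
Title: Dynamical Models of Cyclin-Dependent Kinase Control of the Cell Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ordinary differential equation models of the eukaryotic
    cell-cycle engine, from the time-delayed negative-feedback mitotic
    oscillator of the early frog embryo to the dual-bistable Wee1/Cdc25 and
    Greatwall/ENSA/PP2A:B55 switch network, together with the dynamical
    analysis machinery needed to characterise them: stiff integration,
    limit-cycle detection, checkpoint-arrest classification, a hybrid
    simulator of size-controlled division in fission yeast, multi-start
    steady-state location, pseudo-arclength continuation with fold and Hopf
    detection, SNIC classification by period divergence, and pseudo-nullcline
    computation for phase-plane projections of high-dimensional models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: deSolve, jsonlite, stats, utils, grDevices, graphics
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
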