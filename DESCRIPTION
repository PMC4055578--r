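Package: glossim
Title: Deterministic Grid Simulation of Tsetse Fly Movement and Bait Finding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic lattice model of tsetse (Glossina) movement and
    host/bait finding. Flies diffuse over a grid of 10 m vegetation cells
    ("good", "poor", "no-go") by orthogonal steps with a step probability
    calibrated against the classical random walk; hosts and insecticide-treated
    targets stimulate flies over visual and odor-plume footprints whose ranges
    scale with body mass; a cohort is followed through its six-day hunger
    cycle with background mortality, wild-host feeding and starvation. Drivers
    reproduce habitat-geometry experiments: displacement versus habitat width,
    crossover catch comparisons, odor efficacy, target kill rates, feeding
    success and starvation risk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
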