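Package: monowave
Title: Finite-Difference Simulation of Anisotropic Reaction-Diffusion
    Systems in Excitable Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Explicit finite-difference solver for monodomain
    reaction-diffusion systems in excitable media, aimed at cardiac
    electrophysiology. Provides isotropic and orthotropic diffusion
    stencils with Neumann boundaries and obstacle masks, a menu of
    excitable cell models with wrapper and multi-model composition,
    forward Euler and classic Runge-Kutta time stepping with
    CFL-bounded step selection, stimulation protocols (shapes, stimuli,
    triggers, S1S2), sensors and pseudo-electrogram recording, NPY/YAML/CSV
    output formats, and phase-singularity (spiral-wave tip) detection with
    trajectory linking and activation-time phase-defect analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
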