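Package: tfusim
Title: Transcranial Focused Ultrasound Simulation in a Layered Axisymmetric Head Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates focused ultrasound transmission through a five-layer
    axisymmetric human head model (coupling gel, skin, outer cortical bone,
    trabecular bone, inner cortical bone, brain) with frequency-dependent
    thermoviscous losses parameterized by sound diffusivity. Provides a linear
    frequency-domain Helmholtz solver with an equivalent-fluid loss model and
    perfectly matched layers, and a nonlinear time-explicit solver for the
    conservative first-order Westervelt system with CFL-stable Runge-Kutta
    stepping and a sponge absorber. Includes a scenario factory for regional
    skull geometries (thickness, cortical/trabecular decomposition, radius of
    curvature), tone-burst source synthesis, focal metrics (sound transmission
    loss, maximum pressure ratio, focal depth, 5 percent focus zone, harmonic
    spectra), and parametric sweep orchestration with trend reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
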