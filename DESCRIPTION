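Package: stenoclot
Title: Shear-Gated Wall Permeability and Thrombus Formation in Stenosed Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled hemodynamics and coagulation modelling of intravascular
    thrombus formation near an atherosclerotic stenosis. Solves incompressible
    2D channel flow with a Darcy filtration-resistance feedback from the
    growing fibrin gel, a six-species reaction-advection-diffusion cascade
    (primary activator, cascade activator and inhibitor, fibrinogen, and the
    first two moments of the fibrin polymer length distribution), and a
    piecewise-linear shear-stress-gated wall permeability law. Provides
    finite-volume solvers on body-fitted meshes, polymer-physics closures for
    moment-dependent transport coefficients, regime classification (liquid
    versus clotting), nucleation-time scaling fits, parametric sweeps, and
    flow-topology diagnostics (recirculation zone, separatrix, reattachment).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    grDevices,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
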