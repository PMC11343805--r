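Package: atherofem
Title: Coupled Mechano-Chemo-Biological Finite-Element Simulation of
    Atherosclerosis Initiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the initiation of atherosclerotic plaque growth in an
    idealized artery following the outside-in hypothesis: obstruction of the
    vasa vasorum microvessel network starves the outer wall of nutrients,
    recruits monocytes, and triggers a cascade of macrophage differentiation,
    foam-cell transformation, smooth-muscle-cell attraction and collagen
    synthesis whose accumulated mass drives volumetric growth and lumen
    narrowing.  The mechanical model is an anisotropic hyperelastic continuum
    with collagen fiber remodeling toward a homeostatic prestretch, discretized
    with mixed trilinear hexahedral finite elements (displacement plus
    element-constant pressure and dilatation).  Nutrients obey a steady
    diffusion-reaction equation and immune cells diffusion-advection-reaction
    equations with chemotaxis along the nutrient gradient, solved monolithically
    with backward-Euler time stepping, Gauss-point internal-variable
    condensation and Newton's method.  A stochastic fractal-tree generator
    builds the vasa vasorum network that defines the nutrient supply.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
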