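Package: phytoiop
Title: Coated-Sphere Simulation of Phytoplankton Inherent Optical Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates hyperspectral (400-850 nm) chlorophyll-a-specific
    inherent optical properties of phytoplankton assemblages with a two-layer
    (coated-sphere) Mie scattering model. Complex refractive indices of the
    chloroplast shell and cytoplasm core are built from pigment absorption
    shapes via a discrete Hilbert (Kramers-Kronig) transform and anchored to
    intracellular chlorophyll density, so the pigment package effect emerges
    from cell size and pigment density alone. Per-particle efficiencies,
    volume scattering functions, phase functions and backscatter
    probabilities are integrated over size distributions parameterised by
    effective diameter and effective variance, normalised to 1 mg m-3
    chlorophyll a, and exported as per-group spectral libraries for 17
    phytoplankton groups, including a gas-vacuolate prokaryote variant.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
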