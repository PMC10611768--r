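Package: woolscale
Title: Wool Fibre Cuticle Scale Morphometry and Acid-Dye Diffusion Kinetics
Version: 0.1.0
Authors@R:
    person("Woolscale", "Maintainers", email = "maintainers@woolscale.example", role = c("aut", "cre"))
Description: Tools for characterising the cuticle (scale) morphology of wool
    fibres from electron micrographs and relating it to dye-uptake kinetics.
    Measures fibre diameter, total scale-boundary perimeter per 100 micrometre
    axial window, visible-scale counts (0.5 rule for partially visible
    scales), the dimensionless scale perimeter index (SPI), and the
    diameter-based scale pattern class (coronal, coronal-reticulate,
    reticulate). Estimates apparent dye diffusion coefficients from
    finite-bath uptake time series via the early-phase Hill relation
    Mt/Me = 4*sqrt(D*t/(pi*r^2)), fits the through-origin quadratic linking
    scale perimeter to diameter, and validates new fibre types against the
    fitted correlation framework. Includes a seeded synthetic-data module
    producing fibre images with exact ground-truth scale geometry and
    Fickian-cylinder uptake series, so the whole pipeline is testable
    without micrograph or dye-bath data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
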