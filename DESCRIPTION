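Package: leafhydro
Title: Leaf Hydraulics, Pressure-Volume Analysis and Phylogenetic
    Comparative Methods for Grass Ecophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for leaf water-relations studies in grasses:
    extraction of pressure-volume (PV) curve parameters (turgor loss point,
    osmotic potential at full turgor, apoplastic water fraction, bulk
    modulus of elasticity, bulk leaf capacitance) from bench-drying series,
    nonrectangular-hyperbola fitting of photosynthetic and stomatal light
    responses, leaf hydraulic conductance by the evaporative flux method,
    anatomical trait derivation (vein densities, bundle-sheath area per
    leaf width, carbon-isotope classification of photosynthetic type), and
    a phylogenetic comparative layer (generalised least squares with
    maximum-likelihood Pagel's lambda, Brownian-motion ancestral state
    reconstruction with variances and confidence intervals, tie-corrected
    Kruskal-Wallis tests with compact letter displays, and standardised
    principal component analysis of bioclimatic variables).  Seeded
    forward generators for every input make the whole pipeline testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phytools,
    nlme,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
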