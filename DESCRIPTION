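Package: plumequench
Title: Bacterial Reshaping of Nutrient Plumes Around Sinking Marine Particles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid microscale model of eutrophic plume reshaping around
    sinking marine particles. Couples a data-derived exponential radial
    distribution function (RDF) for clustered free-living bacteria to the
    steady advection-diffusion-uptake equation in Stokes flow past a sphere,
    on an axisymmetric stretched finite-difference grid. Computes microzone
    radii and hotspot indices from RDF parameters, fits RDFs to digitized
    bacterial accumulation profiles by constrained nonlinear regression,
    and derives plume metrics: plume length and volume, length/volume
    quenching factors, nutrient exposure, total fluxes, Sherwood number,
    and dissolution/degradation efficiencies. Includes dimensional analysis
    (Peclet, Damkohler, Reynolds, timescales), screening conditions, particle
    size/velocity classification of aggregate records, batch quenching over
    record tables with a lookup grid, and synthetic-data generators for
    profiles and particle tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    patchwork
Config/testthat/edition: 3
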