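Package: reflmem
Title: Specular Neutron Reflectometry Modelling of Membrane-Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and co-refinement of specular neutron
    reflectometry data from supported lipid bilayers carrying embedded and
    surface-adsorbed proteins. Computes coherent scattering length densities
    with deuteration and solvent H/D exchange, exact slab-model reflectivity
    (Abeles optical matrix with a Parratt-recursion cross-check), Gaussian
    resolution smearing, component volume-fraction profiles, simultaneous
    multi-contrast fitting with bootstrap confidence intervals, and one- and
    two-component exponential-association kinetics for protein binding time
    series. Includes a synthetic-data generator for multi-contrast
    reflectivity curves and kinetic traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
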