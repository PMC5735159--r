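Package: memperm
Title: Membrane Permeation Thermodynamics from Simulated Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the membrane permeation of titratable
    drug-like molecules. Reconstructs permeation free-energy profiles from
    umbrella-sampling windows (WHAM), decomposes them into entropy and
    internal-energy contributions by temperature finite differences,
    computes position-dependent pKa shifts through a thermodynamic cycle,
    estimates water/bilayer partition coefficients (logP) from equilibrium
    trajectories and from free-energy integrals, profiles local
    electric-field fluctuations across the bilayer, summarises translational,
    orientational and conformational degrees of freedom, and surveys analog
    descriptor tables with density-peak clustering and PCA. A synthetic-data
    module generates Boltzmann-consistent inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    MASS,
    pracma,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
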