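Package: wormFAS
Title: Focal Axonal Swelling Injury Dynamics on the C. elegans Connectome
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates single-compartment membrane dynamics with gap
    junctions and graded chemical synapses on the C. elegans somatic
    connectome, injures the network with distributed focal axonal
    swellings drawn from an empirical swelling distribution, and
    quantifies the resulting behavioural deficits. Forward crawling is
    read out as a limit cycle in the two leading SVD modes of the
    forward-motion motorneuron voltages; injury collapses that cycle to
    a fixed point at a critical amplitude found by bisection. Deficits
    are quantified with Procrustes shape analysis of the deformed
    cycles, paralysis endpoints are split into outcome classes along
    their principal axis, and classification trees relate injury
    structure to outcome with cross-validation and shuffled-label
    baselines. Includes seeded synthetic fixtures (toy connectomes, a
    hand-crafted oscillator motif, planted-structure injury ensembles)
    so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, vegan, rpart, optparse, knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'injury.R'
    'neural_modes.R'
    'connectome.R'
    'dynamics.R'
    'attractor.R'
    'behavior.R'
    'fixtures.R'
    'trees.R'
    'shape.R'
    'pipeline.R'
    'utils.R'
    'wormFAS-package.R'
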