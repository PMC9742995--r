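Package: phytoalloc
Title: Macromolecular Allocation Model of Phytoplankton Growth Under
    Nitrate Limitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Steady-state coarse-grained model of phytoplankton growth in
    which cellular carbon and nitrogen are allocated among photosynthetic,
    biosynthetic, essential and storage macromolecular pools. The carbon
    budget yields a quadratic equation for the carbon-limited growth rate
    and the nitrogen steady state (uptake balancing growth dilution) yields
    a cubic equation for the nitrogen-limited growth rate; realized growth
    is their minimum, which reproduces the saturating growth-versus-nitrate
    relationship mechanistically. Includes classical Monod kinetics as a
    reference model, a Metropolis-Hastings engine for fitting either model
    to growth-versus-nitrate datasets, a seeded synthetic-data generator,
    and a pipeline for running full experiments from CSV inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
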