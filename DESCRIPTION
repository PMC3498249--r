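Package: bcri
Title: Forest Recovery Assessment with the Tanner (Bray-Curtis) Recovery Index
Version: 0.1.0
Authors@R: person("bcri", "developers", role = c("aut", "cre"),
    email = "bcri@example.org")
Description: Quantifies the recovery of disturbed forest plots from paired
    census data. Implements the Tanner recovery index (the mean of
    quantitative Bray-Curtis similarities of species composition computed on
    stem density and on basal area), proportionate comparator indices
    (abundance-based Chao-Jaccard and Morisita-Horn), recovery assessment
    normalized by maximum-attainable similarity in temporal and spatial
    (space-for-time) designs, importance values, change tests between
    censuses, individual-based rarefaction, Dufrene-Legendre indicator
    species analysis with Monte Carlo significance, and a seeded generator
    of paired gap/control plot censuses. Ships a command-line interface for
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
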