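Package: thicketbirds
Title: Community Occupancy and Abundance Models for Willow Thicket Bird Surveys
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how the areal extent and spatial
    configuration of riparian willow thickets shape an arctic tundra bird
    community. Provides raster-based landscape metrics (willow area, patch
    density, edge density within a 4-ha quadrat), a data-augmented
    hierarchical multispecies occupancy model fitted by Markov chain Monte
    Carlo with derived species-richness summaries, single-species N-mixture
    abundance models fitted by maximum likelihood, inverse-variance
    meta-analytic pooling of species effects into assemblage-level
    estimates, and a synthetic-data generator emulating the repeated
    point-count study design (3 regions, 37 points, 4 years, 3 visits).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
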