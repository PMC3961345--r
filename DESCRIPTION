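Package: travelfriend
Title: Coupled Human Mobility and Social-Tie Formation on Population
    Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of the travel-and-friend process, in
    which agents move over a population-density raster (visiting friends
    or taking density-guided random jumps with heavy-tailed lengths) and
    form directed social ties through spatial encounters and global
    random links. Provides distance-resolved geo-social network
    statistics (link probability, reciprocity, social overlap,
    clustering, triangle disparity), uncoupled spatial and linking null
    models, Latin-square model calibration with a multi-property error,
    and a mean-field integrator for the linking model's master
    equations. Includes readers and writers for ESRI ASCII rasters,
    edge-list and location tables, and check-in records, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    geosphere,
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
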