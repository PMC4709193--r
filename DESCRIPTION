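Package: juriflux
Title: Jurisdictional Forest Carbon Flux Accounting with Comprehensive
    Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements an elaborated IPCC gain-loss method for estimating
    jurisdictional forest carbon fluxes: stratify-and-multiply benchmark
    biomass mapping from lidar-footprint samples (one-way ANOVA with Tukey
    lumping of candidate strata), annualized activity data extracted from
    forest loss/gain rasters and government logging records, a process-based
    forest loss factor with linear dead-wood decay, wetland (peat and
    mangrove) soil carbon emission rules, selective-logging degradation
    factors, and Monte Carlo propagation of every parameter's uncertainty
    with group-wise source attribution.  A synthetic-jurisdiction generator
    with analytically known true fluxes makes the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Software
RoxygenNote: 7.3.3
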