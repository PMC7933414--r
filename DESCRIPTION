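Package: RootRD
Title: Reaction-Diffusion Modelling of Tooth Root Patterning and Dental
    Trait Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates two-dimensional cell patterns of developing tooth
    roots with an activator-inhibitor reaction-diffusion system running on
    a growing, mechanically relaxed polygonal cell network (vertex model),
    and classifies the resulting activator fields into root-type patterns
    (one to four roots, C-shaped). Also implements the genotype-phenotype
    association statistics used for dental traits: exact r x c contingency
    tests (Freeman-Halton), logistic regression with Wald tests, and
    Spearman rank correlations with tied ranks, together with a synthetic
    cohort generator that emulates the published EDAR 370V/A study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
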