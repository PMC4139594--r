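Package: vznet
Title: Knowledge-Based Discovery of Ventricular Zone Gene Networks in the
    Developing Neocortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for knowledge-based discovery of candidate
    regulators of early neocortical development. Builds spatial co-expression
    networks from structure-by-age expression atlases (a ventricular-zone
    network at the peak of neurogenesis), runs dual differential-expression
    screens (spatial zone contrast and early-developmental-stage contrast)
    with a six-fold filter and Holm-Bonferroni family-wise control,
    intersects the resulting mouse and human gene lists across species,
    extends candidate lists by label propagation over multi-evidence
    association networks, and scores gene-set over-representation with a
    hypergeometric test under Benjamini-Hochberg false-discovery-rate
    control. Includes seeded synthetic-data generators that emulate the
    statistical structure of developmental brain atlases (planted
    co-expressed zone-specific modules, log-normal noise) so that every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
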