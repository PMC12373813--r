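Package: SocioSpace
Title: Socio-Spatial Behavior Analysis for Co-Housed Primate Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing simultaneous 3D position recordings of
    co-housed primates in an enclosure. Provides a synthetic multi-animal
    trajectory generator with individual spatial footprints, pairwise
    attraction and occlusion gaps; normalized occupancy maps and a
    context-change index with a resampled permutation test; pairwise
    identity decoding from instantaneous position (RBF support vector
    machines with shuffled-label nulls, within-session, cross-session and
    cross-context protocols); interpersonal-distance proxemics (distance
    distributions, data-driven affiliation thresholds, affiliative
    strength and weakness, close-proximity bout statistics); and a
    two-agent wall-constrained lattice random walk with a stay-together
    rule, including grid-search fitting of the stay probability to an
    empirical distance distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
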