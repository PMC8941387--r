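Package: facemasc
Title: Landmark-Based Facial Masculinity Scoring and Family-Group Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying facial masculinity from
    three-dimensional facial landmarks. Computes Euclidean and surface
    (geodesic) distances between 21 named Farkas craniofacial landmarks on
    triangulated face meshes, selects sexually dimorphic distances by
    cross-validated forward search, fits a two-class Fisher linear
    discriminant separating male and female faces, and scales the signed
    discriminant projection to a 0-1 masculinity score. Group differences
    (e.g. parents of autistic versus non-autistic children) are tested per
    variable with a 2x2 factorial ANCOVA adjusting for facial area and age,
    with Bonferroni-corrected alpha and covariate-adjusted standardized
    effect sizes. Includes a calibrated synthetic face-cohort generator for
    validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
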