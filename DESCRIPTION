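Package: pubicorridor
Title: Safe Screw Corridor Planning in the Pubic Body on Triangulated Bone Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans the two obliquely inserted screws that anchor a pelvic
    reconstruction plate placed lateral to the pubic tubercle. Reads
    triangulated hemipelvis surface meshes (STL/PLY, millimetres) with named
    anatomical landmarks, constructs the offset pelvic-brim curve and the
    plate's innermost insertion sites, finds the obturator-tangential screw
    and the maximal anterior/posterior inclination angles and screw lengths by
    cylinder-in-mesh containment searches, classifies the projected safe
    insertion region, and reproduces the cohort summary statistics
    (pooled two-sample t tests from per-sex summaries, Kolmogorov-Smirnov
    normality screens, three-table reports). Includes a parametric bone
    phantom generator (analytic strip phantoms with a closed-form tilt oracle,
    pubis phantoms with obturator foramen and tubercle, virtual cohorts drawn
    from sex-specific morphometric distributions) so every measurement can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
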