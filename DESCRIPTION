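Package: needleplan
Title: Condition-Based Access-Path Planning for Percutaneous Needle
    Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated planning of percutaneous needle access paths on
    triangle-mesh anatomy. Candidate insertion points are sampled on a
    skin surface mesh, screened against hard admissibility conditions
    (risk-structure clearance, needle length, insertion angle,
    line of sight) and rated by three soft condition quality values
    (distance to risk structures, relative path length, angle to the
    transverse imaging plane) aggregated by their minimum. Includes a
    synthetic phantom generator (analytic slab scenes and torso-like
    ellipsoid phantoms with embedded risk structures), quality-class
    heatmap and vertex-colour rendering, target-depth overlay geometry,
    mesh input/output for STL, OBJ and PLY, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    grDevices,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
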