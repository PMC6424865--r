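Package: sqwell
Title: Square-Well Fluid Thermodynamics of Concentrated Macromolecular Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models non-specific protein-protein interactions in concentrated
    solution as a single-species square-well fluid. Computes concentration-
    dependent thermodynamic activity coefficients by an analytical route
    (scaled particle theory hard-core term plus a truncated Kihara soft-virial
    term) and by event-driven molecular dynamics with Widom particle
    insertion; predicts colligative observables (static light scattering,
    sedimentation-equilibrium apparent molar mass, osmotic pressure) and
    constructs liquid-liquid phase-separation diagrams (spinodal, binodal,
    critical point, lever rule, reduced coexistence curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
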