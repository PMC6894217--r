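Package: gravicap
Title: Membrane Tension of a Gravity-Loaded Vesicle Cap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Static-equilibrium model of a gravity-loaded vesicle ("water sac")
    spreading on a rigid substrate. Fits pseudo-ellipsoidal and pseudo-spherical
    cap loci to spreading-state morphometry (contact area, height, volume),
    solves the adhesion and force-balance chain (JKR contact radius, volume-
    conserving effective cap height, contact angle, Young wetting tension,
    basal pressure), and evaluates closed-form membrane-tension fields along
    the free membrane, including a residual checker for the underlying
    axisymmetric equilibrium equations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
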