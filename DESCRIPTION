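Package: icaflow
Title: Lumped-Parameter Hemodynamics of the Internal Carotid Artery Tree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Zero-dimensional pulsatile blood-flow model of the internal
    carotid artery and its intracranial branches (ophthalmic, anterior
    cerebral, and the M1/M2 segments of the middle cerebral artery) with
    two-element Windkessel outlet boundary conditions, Carreau shear-thinning
    blood rheology, and Hagen-Poiseuille conduit mechanics. Maps fractional
    diameter stenosis to distal resistance, calibrates outlet resistances
    against plane-averaged velocity targets, and derives branch-sensitivity
    statistics, reverse-flow onset thresholds, and fractional flow reserve
    from stenosis severity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
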