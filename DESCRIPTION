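Package: hemeQuant
Title: Comparative Quantification of Labile Heme and Hemoglobin in Plasma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spectrophotometric quantification of cell-free hemoglobin and
    labile heme in plasma. Implements the Harboe three-wavelength
    polychromatic correction, direct UV/Vis Soret-band calibration, the
    pyridine hemochromogen assay under several extinction-coefficient
    conventions, surfactant (SLS) and colorimetric kit read-outs,
    peroxidase-reconstitution (apoHRP) and reagent-strip methods, together
    with a combined Harboe plus kit estimator that corrects the kit signal
    for the hemoglobin contribution to report labile heme. Includes a
    Beer-Lambert forward simulator for plasma absorbance spectra and assay
    read-outs with known ground truth, ICH-style validation statistics
    (recovery, mean recovery rate, 15 percent linearity rule, LOD/LOQ),
    automatic dilution-factor selection, and hemolysis/icterus/lipemia
    sample classification for panel reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'registry.R'
    'calibration.R'
    'componentLibrary.R'
    'simulate.R'
    'quantifiers.R'
    'pipeline.R'
    'io.R'
    'cli.R'
    'hemeQuant-package.R'
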