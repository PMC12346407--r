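Package: axstab
Title: Oxidative Stability Analytics for Antioxidant-Enriched Fats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for shelf-life studies of lipid matrices
    enriched with a carotenoid antioxidant. Quantifies astaxanthin by
    first-derivative UV-Vis spectrophotometry (windowed derivative peaks and
    areas under the curve, calibration curves, first-order degradation
    kinetics), detects the oxidation onset temperature on differential
    scanning calorimetry curves and estimates activation energies by the
    Ozawa-Flynn-Wall isoconversional method, fits second-order response
    surface models with full inference panels and backward term elimination,
    optimizes the antioxidant concentration with Derringer desirability
    functions, and validates models by Bland-Altman agreement analysis.
    Includes synthetic-data generators with known ground truth for spectra,
    oxidation exotherms and design tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
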