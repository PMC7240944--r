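Package: mzFBA
Title: Annotating Untargeted LC-MS Features Against Flux Balance
    Analysis Metabolite Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Correlates significantly changing features from untargeted
    liquid chromatography mass spectrometry experiments with metabolite
    lists predicted by genome-scale flux balance analysis models (and
    with full compound databases such as ModelSEED). Features are
    annotated by accurate-mass adduct matching at ppm tolerance, grouped
    by co-elution into peak groups, and validated against M+1 isotope
    ratios measured in the raw centroided spectra. Includes readers for
    XCMS-style feature tables, model/database compound exports and
    mzXML/mzML raw data, a synthetic-data generator with planted ground
    truth, ranked match tables, summary counts and 3D visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    lattice,
    jsonlite,
    mzR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
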