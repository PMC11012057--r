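Package: herbmarker
Title: Quality-Control Marker Screening and Metabolite Annotation for
    Untargeted LC-MS/MS of Herbal Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening quality-control markers and annotating
    metabolites from aligned LC-MS/MS feature tables of herbal samples.
    Provides exact monoisotopic mass arithmetic with electron-corrected
    adduct rules and brute-force CHNO formula enumeration; a stepwise
    feature-filtering cascade (peak-rating and intensity quality filters,
    element filters, one-way ANOVA with Tukey post-hoc and
    Benjamini-Hochberg adjustment, PLS-DA variable importance, top-N
    ranking, hierarchical clustering); detection and collapse of coeluting
    adduct and in-source-fragment satellite features; and rule-based
    compound identification via diagnostic product ions, an in-house
    compound database, and spectral-library matching. Includes readers and
    writers for feature-table CSV, MGF spectra, MSP libraries, and compound
    database CSV, and a synthetic-study generator with full ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
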