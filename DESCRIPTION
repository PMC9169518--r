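Package: citrusOHA
Title: Oxygenated Heterocyclic Aglycone Profiling and Authenticity
    Assessment of Citrus Juices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted profiling of oxygenated heterocyclic aglycones (OHAs,
    i.e. methoxyflavones, coumarins and furanocoumarins) in citrus juice by
    HPLC with diode-array and fluorescence detection, and chemometric
    assessment of juice authenticity.  Provides a reference compound
    catalog; peak identification by full-spectrum conformity, fluorescence
    peak-height ratios and alkylarylketone retention indices; empirical
    spectral rules that assign substitution classes to unknown OHAs;
    through-origin calibration with internal-standard correction and
    LOD/LOQ estimation; sample-by-compound profile matrices with
    relative-weight normalisation; PLS1 regression with full
    cross-validation and Martens' jackknife uncertainty test for variable
    reduction; exhaustive virtual-blend purity models for detecting
    mandarin juice in orange juice and pomelo juice in grapefruit juice;
    and a synthetic-data generator so the whole pipeline can be exercised
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
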