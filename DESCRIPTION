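Package: nodeconcord
Title: Preoperative CT vs Histology Lymph-Node Concordance for Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the concordance between preoperative
    contrast-enhanced CT assessment of abdominopelvic lymph nodes and the
    postoperative histopathological report in colorectal cancer, using a
    JSCCR-style map of nodal stations grouped into locoregional,
    intermediate and central distance bands. Implements the
    size-conditional suspicion rule for CT-visible nodes, the five-value
    enhancement-pattern vocabulary, station-level concordance categories,
    the suspicious-to-positive ratio (SPR) and lymph node ratio (LNR),
    Pearson chi-square with expected counts and cell contributions,
    odds ratios with Woolf confidence intervals and Haldane-Anscombe
    zero-cell correction, and diagnostic metrics. Includes a seeded
    synthetic cohort generator whose pattern-conditional metastasis
    probabilities are calibrated to target odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
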