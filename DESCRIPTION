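Package: pharmakeyword
Title: Pharmacovigilance Keyword Detection in Social-Media Post Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate adverse-event keywords for drugs from
    collections of social-media posts. Posts mentioning a drug (by brand or
    generic name) are assembled into per-drug corpora and compared against
    control corpora by per-word one-tailed Welch t-tests on word frequencies,
    with Benjamini-Hochberg retention of the ranked significant-word list.
    Includes a seeded synthetic corpus generator (Zipf background vocabulary,
    configurable drug-mention prevalence, planted signal words at controlled
    rate ratios) so the whole pipeline can be exercised and calibrated
    without access to the original forum data, plus recovery metrics for
    planted signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
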