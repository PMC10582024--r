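Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on individual case
    safety report (ICSR) databases. Provides a normalized CSV data model for
    spontaneous reports, standardized MedDRA query (SMQ) style case
    definitions at the preferred-term level, dual-comparator two-by-two
    disproportionality analysis (proportional reporting ratio, reporting odds
    ratio, and the shrinkage information component with its IC025 credibility
    bound), conjunctive signal classification, descriptive safety tabulations
    (demographics, seriousness, outcomes, dechallenge), and a synthetic ICSR
    generator with planted drug-event signals and full ground-truth
    bookkeeping for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
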