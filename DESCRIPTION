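Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("FAERS", "Signal Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of FDA Adverse Event
    Reporting System (FAERS) quarterly ASCII archives: ingestion and linkage
    of the dollar-delimited DEMO/DRUG/REAC/OUTC/RPSR/THER/INDI tables,
    case deduplication by case version, age normalization and adolescent
    cohort extraction, sex-stratified frequency tables for drugs, reactions
    and indications, and disproportionality statistics against a designated
    control event: reporting odds ratio (closed form and logistic
    regression), proportional reporting ratio, and relative reporting
    ratio, with Wald confidence intervals. Includes a synthetic FAERS
    quarter generator with configurable drug-event association strengths
    so every pipeline stage can be exercised without downloading archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
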