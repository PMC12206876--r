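Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance signal-detection pipeline for FAERS-style
    spontaneous adverse-event report extracts: ingestion of '$'-delimited
    quarterly ASCII tables (DEMO, DRUG, REAC, THER, INDI), case-level
    deduplication by CASEID/FDA receive date/PRIMARYID, drug-name and
    MedDRA-style term normalisation, 2x2 contingency tables at preferred-term
    and system-organ-class level, four disproportionality statistics
    (reporting odds ratio, proportional reporting ratio with chi-square,
    BCPNN information component, and a gamma-Poisson shrinker EBGM) with
    configurable signal gating, sex/age subgroup and concomitant-medication
    sensitivity re-analysis, Weibull time-to-onset modelling, and a synthetic
    FAERS-like corpus generator with ground-truth sidecars for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
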