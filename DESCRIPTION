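Package: gisignal
Title: Disproportionality Signal Detection for Drug-Induced Gastrointestinal
    Ulcer Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance analysis of spontaneous
    adverse-event reports in the FAERS quarterly-file format, centred on
    NSAID-induced gastrointestinal ulcer events. Reads and merges DEMO/DRUG/REAC
    tables, deduplicates case versions, restricts to oral administration, and
    normalizes drug names; computes reporting odds ratios from Haldane-corrected
    2x2 contingency tables with Woolf confidence intervals and two-sided Fisher
    exact p-values; builds volcano tables, demographic stratum analyses, an
    events-by-drugs log-ROR matrix, correlation-matrix principal component
    analysis, and Ward hierarchical clustering of drugs with elbow-based
    cluster-count selection. Includes a synthetic report generator with known
    injected log-odds signals so every stage is testable without the full
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
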