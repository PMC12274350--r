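Package: dlbtext
Title: Case-Finding for Dementia with Lewy Bodies in Free-Text Clinical Records
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects the four core clinical features of dementia with Lewy
    bodies (visual hallucinations, cognitive fluctuations, parkinsonism and
    REM sleep behaviour disorder) in free-text clinical notes using keyword
    lexicons with negation and uncertainty handling, aggregates mention-level
    output to patient-level symptom profiles scored against possible/probable
    DLB criteria, and compares demographics and symptom prevalence between
    diagnostic groups with Welch t-tests and chi-squared tests. Ships a seeded
    synthetic electronic-health-record corpus generator with gold-standard
    span annotations and an evaluation harness computing per-concept precision
    and recall.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    stringr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
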