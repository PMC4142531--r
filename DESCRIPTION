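Package: aersdm
Title: Standardize and Aggregate FDA Adverse Event Reports with RxNorm,
    NDF-RT and MedDRA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a normalized drug/adverse-event data set from FDA
    Adverse Event Reporting System (AERS/FAERS) quarterly ASCII tables.
    Applies the FDA-recommended de-duplication rule (latest FDA_DT per
    CASE, ties broken by highest ISR), normalizes free-text drug entries
    to RxNorm concepts with a lexicon matcher or an adapter for external
    MedEx output, classifies concepts into NDF-RT multi-axial drug
    classes by greedy breadth-first traversal of RxNorm relationships,
    rolls MedDRA Preferred Terms up to System Organ Classes, and emits
    normalized and aggregated drug/event tables with coverage statistics
    and precision/recall evaluation metrics. Includes a deterministic
    generator of miniature RxNorm, AERS and MedDRA-style fixtures with
    recorded ground truth for fully offline testing.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
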