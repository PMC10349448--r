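Package: migrwe
Title: Dual-Arm Real-World-Evidence Concept Extraction and Evaluation for Migraine EHR Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for emulating and evaluating a dual-arm real-world-evidence
    (RWE) study of migraine in electronic health records. A "Traditional" arm
    identifies migraine-related concepts from structured fields (problem list,
    medication list, encounter claims) through code-map queries; an "Advanced"
    arm applies rule-based natural language processing to free-text notes,
    including sentence-scoped negation, temporality and severity detection,
    sign-prefixed template parsing with encounter-level support inference, and
    abbreviation disambiguation over the patient's longitudinal record. Both
    arms are scored against a reference standard with encounter-level recall,
    precision and F1, chi-square arm comparisons, and Cohen's kappa
    inter-annotator agreement. A seeded synthetic EHR corpus generator with
    exhaustive ground truth emulates the documentation-completeness gap between
    structured and narrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
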