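Package: gastroie
Title: Rule-Based Extraction of Gastric Disease Information from
    Endoscopy Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A rule-based clinical natural language processing pipeline
    that extracts structured information (presence, anatomical extent,
    location, ulcer stage, lesion size) for ten gastric diseases from
    free-text esophagogastroduodenoscopy (EGD) reports and linked
    pathology reports.  Includes a bilingual lexicon format with
    longest-match term scanning, organ-based section segmentation,
    window-based negation detection, impressions-to-findings concept
    mapping, pathology-based classification of neoplastic disease,
    per-variable evaluation against gold-standard annotations
    (sensitivity, positive predictive value, accuracy, F1), cohort-level
    prevalence and extent/location aggregation, and a synthetic report
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
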