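Package: ackminer
Title: Mining Antibody Donations from Article Acknowledgement Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts antibody donation statements (donor, donor affiliation,
    antibody name, antibody attributes) from the acknowledgement sections of
    biomedical full-text articles. Provides a shallow JATS/PMC XML
    acknowledgement parser, a rule-based context-window extractor anchored on
    antibody keyword mentions, a bootstrapped pattern learner that induces
    extraction patterns from the noun phrases around seed antibody names, a
    gold-annotation XML format with readers and writers, per-field evaluation
    against multiply-annotated gold standards, a deterministic synthetic
    acknowledgement-corpus generator with known ground truth, and corpus-level
    aggregation (top donors, donated antibodies, yearly donation trends).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringi,
    tibble,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
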