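Package: pgxcds
Title: Rule-Based Pharmacogenomic Clinical Decision Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for representing pharmacogenomic (PGx) drug-label
    knowledge as formal if-then decision-support rules and for analysing
    their deployability. Provides a typed rule model with a YAML
    interchange format; a certainty-lexicon classifier that assigns each
    consequent statement a presentation type (information only,
    recommendation, or warning); a forward-chaining supporting-knowledge
    engine that derives intermediate clinical facts (e.g. poor-metabolizer
    phenotype from a star-allele diplotype); a patient-level rule
    evaluator under Kleene three-valued logic so missing clinical data
    yields an indeterminate status rather than a silent non-fire; an EMR
    data-availability coverage analyser over three nested scenarios (EMR
    alone, plus supporting knowledge, plus feasible expansion); and
    evidence-catalog statistics (citation-set overlap, evidence-category
    distributions, encoded-knowledge matrix summaries). Seeded synthetic
    generators and transcribed fixtures make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
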