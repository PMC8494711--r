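Package: nephroprior
Title: Phenotype-Driven Variant Prioritization for Inherited Kidney Disease Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a clinical-exome variant prioritization workflow for
    monogenic kidney disease: phenotype-tailored virtual gene panels with a
    two-pass stop rule, sequential quality/frequency/consequence filters with a
    per-variant audit trail, inheritance-mode and digenic candidate logic,
    trio segregation, a reduced ACMG-style five-tier classifier, report
    inclusion rules, cohort-level diagnostic-yield summaries, panel versioning
    with re-analysis of negative cases, and a seed-deterministic synthetic
    cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
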