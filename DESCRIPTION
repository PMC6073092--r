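Package: percentaudit
Title: Audit of Decimal-Place Presentation of Percents in Biomedical Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based audit of how percents are presented in the abstracts
    of biomedical research articles. Extracts every percent mention from
    abstract text, excludes percents that label statistical intervals or
    significance levels (e.g. "95% CI"), classifies each remaining percent
    against an operationalisation of Cole's presentation guidelines for the
    ideal number of decimal places (too few, just right, too many), applies
    digit-preference and natural-upper-bound sensitivity exclusions, and
    summarises category proportions with Dirichlet-multinomial credible
    intervals. Includes a synthetic-corpus generator with planted ground
    truth so the whole pipeline is testable without any corpus download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
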