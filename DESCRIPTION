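Package: srsmine
Title: Disproportionality Signal Mining for Spontaneous ADR Reporting Systems
Version: 0.1.0
Authors@R: person("SRS", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for spontaneous reporting system (SRS)
    data on antipsychotic drugs: validates case reports, standardizes drug and
    reaction names against ATC and MedDRA-style dictionaries, applies
    inclusion/exclusion criteria, expands reports into drug-event combinations,
    and detects safety signals with four disproportionality methods (ROR, PRR,
    the MHRA PRR/chi-squared rule, and the BCPNN information component).
    Also produces descriptive safety tables, a logistic risk-factor model of
    serious reactions, off-label signal annotation, and a synthetic SRS
    generator with analytic ground truth for method validation.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
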