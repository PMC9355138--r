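Package: peercrowds
Title: Peer Crowd Instrument Scoring, Reliability, and Construct Validity
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scoring and validation tooling for adolescent peer-crowd
    segmentation surveys. Scores a seven-question ranked-choice mindset
    instrument and a photo-grid instrument onto five peer-crowd subscales
    (Alternative, Country, Hip Hop, Mainstream, Popular), plus auxiliary
    health scales (adverse childhood experiences, brief resilience, social
    prioritization, brief sensation seeking). Computes McDonald's omega
    reliability from a one-factor model, builds the 10x10 multi-trait
    multi-method matrix across the two instruments, applies convergent and
    discriminant validity decision rules, and runs a covariate-adjusted
    logistic/linear regression battery relating crowd scores to behaviors,
    experiences, and traits. Ships a synthetic-cohort generator with a known
    latent crowd structure so that every stage can be exercised against a
    recoverable ground truth, and a command-line pipeline that runs
    generate, score, validate, predict end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
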