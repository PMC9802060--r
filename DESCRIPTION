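Package: courtback
Title: Return to Sport and Return to Performance After Severe Lower
    Extremity Injury in Professional Basketball
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveillance-style analysis of time-loss injuries in
    professional basketball. Links roster transaction logs with per-player
    game logs at the individual-game level to construct time-loss injury
    events, classifies events by severity band (Slight, Minor, Moderate,
    Severe) and body region, builds a self-controlled pre/post cohort around
    each player's primary severe lower-extremity injury, and estimates the
    prevalence of return to preinjury performance with Wald confidence
    intervals alongside prognostic post-on-pre linear regressions,
    minutes-controlled and covariate-adjusted models, one-way analysis of
    variance of return-to-sport time by body region, and restricted cubic
    spline sensitivity analyses. A synthetic league generator with known
    ground truth (schedule, box scores, transaction log, roster metadata)
    makes every pipeline stage testable without any external data source.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    splines,
    withr,
    optparse
Config/testthat/edition: 3
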