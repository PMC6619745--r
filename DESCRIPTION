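Package: cmjfatigue
Title: Countermovement-Jump Force-Time Analysis of Metabolic and
    Neuromuscular Fatigue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring athlete fatigue from countermovement-jump
    (CMJ) force-plate recordings. Extracts the concentric phase and four
    scalar features (relative peak force, relative peak power, concentric
    duration, time to peak force) from raw force-time traces; performs
    principal component analysis of features stratified by measurement time
    point, and multivariate functional principal component analysis of
    penalised b-spline smoothed force curves; and fits random-intercept
    linear mixed-effects models, with leave-one-athlete-out cross-validation
    and likelihood-ratio comparisons, to predict relative peak force 6 h
    (metabolic fatigue) and 48 h (neuromuscular fatigue) after training.
    Includes a seeded synthetic-cohort generator emulating a 10-athlete,
    three-workload, eight-time-point study design with two-compartment
    (metabolic + neuromuscular) fatigue time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    pracma,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
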