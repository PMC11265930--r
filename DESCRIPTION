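Package: latchseq
Title: Sequence Analysis of Multi-Solution Puzzle-Box Event Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing RFID event logs from multi-compartment
    puzzle-box experiments with free-ranging animals. Segments timestamped
    detection and door-opening records into visits (trials), classifies
    solvers and social testing conditions, and characterises extractive
    foraging technique as a categorical sequence over latch types: a
    per-trial complexity index combining longitudinal entropy and
    transition rate, and pairwise optimal-matching dissimilarities with
    substitution costs derived from observed transition rates. Includes
    chi-squared latch-preference tests, Mann-Whitney comparisons of
    intra- and inter-individual dissimilarity, forward-stepwise binomial
    GLM competition with AICc, likelihood-ratio tests and Akaike weights,
    and a seeded generator of synthetic event logs with individual latch
    preferences, sticky switching, competition-dependent preference
    sharpening and work-time learning curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
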