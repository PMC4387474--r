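Package: igtmatch
Title: Operant Analysis of Iowa Gambling Task Performance and
    Matching-Law Sensitivity Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses two laboratory decision-making tasks
    from an operant perspective. Provides a deterministic Iowa Gambling
    Task (IGT) engine with the standard four-deck payoff schedule,
    proportional net scores, blockwise deck-preference and switching
    analyses, impairment classification, and an operant-style stability
    criterion for individual learning trajectories. Also simulates a
    two-deck concurrent variable-interval card task with dependent
    (Stubbs-Pliskoff) scheduling and independent reward and penalty
    streams, and estimates generalized-matching-law sensitivity and bias
    from blockwise log response and reinforcer ratios. Synthetic
    reinforcement-learning and matching agents generate cohorts with
    known ground truth for parameter-recovery validation, and
    cross-task reports compare good and poor decision makers with
    Mann-Whitney U tests and rank-biserial effect sizes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
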