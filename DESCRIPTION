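Package: mptswitch
Title: Multinomial Processing Tree Analysis of Error Types in Task Switching
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for disentangling task-selection failures from
    task-execution failures in cued task-switching experiments.
    Implements the three classification paradigms used in the field
    (univalent response sets, bivalent stimuli with congruency
    manipulation, and the three-key target/distractor design),
    multinomial processing tree (MPT) models fitted per participant by
    maximum likelihood, derived conditional failure probabilities, a
    trial-level synthetic-data generator with an injectable N-2
    repetition-cost effect and a slow error-correction mechanism, the
    standard trial- and participant-level trimming rules, and the
    downstream N-2 repetition-cost analysis (repeated-measures ANOVA
    with partial and generalized eta squared, paired contrasts with
    Cohen's dz, and permutation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
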