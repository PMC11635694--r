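Package: capdyn
Title: Co-Activation Pattern Dynamics and Corticostriatal Configuration Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pharmacological modulation of resting-state network
    temporal dynamics with co-activation pattern (CAP) frame assignment and
    dwell metrics (total time, transitions, persistence), computes
    corticostriatal configuration profiles and their divergence metrics
    (aggregate divergence, rank-order rearrangement, entropy shift) against a
    within-session placebo split-half null, and provides the inferential layer
    linking the two: repeated-measures ANOVA with covariates, Bonferroni
    post hocs with effect sizes, a mixed model for network anticorrelation,
    and Steiger's test for dependent overlapping correlations. Includes a
    synthetic cohort generator with planted Markov state dynamics and
    corticostriatal weight structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
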