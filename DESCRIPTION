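Package: fearfield
Title: Behavioral and Place-Cell Analysis for Head-Fixed Contextual Fear
    Conditioning in Virtual Reality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies conditioned fear and hippocampal spatial coding in
    head-fixed mice navigating virtual-reality linear tracks. Provides
    freezing detection from treadmill velocity, lap segmentation and per-lap
    behavioral metrics, context-discrimination deltas, place-field detection
    from calcium (dF/F) traces with a lap-rotation bootstrap null,
    within- and across-session remapping statistics, the accompanying
    statistical layer (paired tests, paired Cohen's d, Bonferroni
    correction, Kolmogorov-Smirnov comparisons, linear mixed-effects
    extinction models), and seed-deterministic synthetic-data generators
    with ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
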