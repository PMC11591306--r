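Package: circlelearn
Title: Reward-Based Circle-Drawing Motor Learning: Task Engine, Metrics and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a reward-based motor-learning task in which
    participants draw circles without visual feedback and receive only binary
    reward. Provides trajectory geometry (arc-length resampling, radius,
    aspect ratio, circularity gating), the closed-loop adaptive reward
    criterion (fifth-largest of the past ten relative radius errors), a
    generative simulator of reward-gated exploratory learners,
    per-participant outcome metrics (fraction learned, reward-conditioned
    trial-to-trial ratios, success frequency, exclusion rules), and the
    nonparametric statistical battery used at the group level (one-sided
    Wilcoxon signed-rank, paired Wilcoxon, Mann-Whitney U, linear regression
    on capped age, Pearson chi-square, Cronbach's alpha, Gaussian-kernel
    smoothing in log-age).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
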