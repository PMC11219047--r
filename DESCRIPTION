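Package: cavalus
Title: Development and Evaluation of Composite Ultrasound Congestion
    Scores in Rodent Heart Failure Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to develop and evaluate composite congestion scores that
    combine inferior vena cava (IVC) imaging with lung ultrasound (LUS)
    findings in small-animal heart failure models. Provides a seeded
    synthetic cohort generator with a latent congestion-severity factor,
    configurable ordinal scoring rubrics, from-scratch implementations of
    the statistical procedures involved (Pearson correlation, Shapiro-Wilk
    normality gating of two-group comparisons, exact and approximate
    Mann-Whitney tests, ROC curves with Youden's J cutoff selection, and
    Bland-Altman agreement), an exhaustive component-combination search
    ranked by a score-correlation matrix against echocardiographic and
    gravimetric reference metrics, observer-agreement analysis, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
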