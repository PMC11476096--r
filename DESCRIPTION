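Package: hjorth2d
Title: Two-Dimensional Hjorth Descriptors for Texture Analysis of
    Pollen Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the three Hjorth descriptors (Activity, Mobility,
    Complexity), originally defined for one-dimensional EEG signals,
    on two-dimensional grayscale images via non-directional
    gradient-magnitude fields. Provides the image preparation pipeline
    (grayscale conversion, min-max normalization, smoothing), the
    rank-based statistics used to differentiate groups of images
    (Kruskal-Wallis ANOVA on ranks, Dunn's post hoc test with
    Bonferroni correction, Levene's test, Shapiro-Wilk), a seeded
    synthetic texture generator for cohort-level testing, and a small
    command-line interface for batch descriptor extraction and group
    comparison. Developed for pre-screening bee pollen micrographs in
    honey authentication workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jpeg,
    jsonlite,
    methods,
    pixmap,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
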