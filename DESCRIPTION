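Package: StressBattery
Title: Multidimensional Behavioral Profiling of Stress Resilience and
    Susceptibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multivariate analysis of rodent behavioral test
    batteries contrasting stressed and non-stressed groups. Provides a
    SummarizedExperiment-backed container for rats-by-variables data with
    test membership and resilience/susceptibility valence metadata,
    univariate battery statistics (t / rank-sum routing by normality,
    Levene variance tests, chi-squared association, inter-rater agreement),
    feature clustering with a sign-independent Euclidean distance and
    subsampling permutation reliability, PCA with shuffled-data nulls and
    split-data component reliability, variance-inflation screening, linear
    discriminant classification on cumulative principal components,
    helplessness classification and individual profile clustering with
    silhouette-based and semi-supervised cluster-number selection, and a
    synthetic battery generator that plants the latent structure these
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    cluster,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
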