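Package: commchart
Title: Multivariate Control Charts and Distance-Based Tests for
    Monitoring Variable Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects change in rare, highly variable communities that lack
    experimental controls.  Provides Bray-Curtis community analysis on
    fourth-root transformed abundances, group-average clustering with
    SIMPROF significance tests, distance-based permutational ANOVA
    (one-way and two-way crossed mixed models with Type III sums of
    squares, permutation of residuals under a reduced model, pairwise
    comparisons and components of variation), permutational tests of
    multivariate dispersion, and multivariate control charts of
    centroid deviations with bootstrapped percentile control limits.
    Includes a synthetic community generator emulating replicated
    plot-by-year lagoon survey designs with overdispersed counts and
    injected press or pulse disturbances, so the whole workflow is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    vegan,
    ape,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
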