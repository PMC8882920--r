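Package: voweldisp
Title: Dispersion, Focalization, and Correlated Evolution of Vowel Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the acoustic structure of vowel systems and
    its evolution across languages. Converts formant frequencies to the Bark
    psychoacoustic scale, computes per-system structural statistics (geometric
    mean pairwise dispersion, convex-hull acoustic space area, effective
    dispersion per unit area, and the focalization estimate), and quantifies
    the power-law dependence between effective dispersion and focalization via
    Spearman correlation, log-log regression, and nested random-intercept
    mixed models, overall and stratified by geographic region and language
    family. Phylogenetic comparative methods test whether the two properties
    evolve in a correlated way on a language phylogeny: Felsenstein
    independent contrasts, maximum-likelihood dependent vs independent
    bivariate Brownian-motion models, and phylogenetic generalized least
    squares under Brownian-motion and Ornstein-Uhlenbeck covariance with a
    likelihood-ratio comparison. A synthetic-data module generates vowel
    typologies, Yule trees, and traits evolved along trees under known
    parameters so every estimator can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
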