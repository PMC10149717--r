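Package: dyadlink
Title: Dyadic Analysis of Milk and Infant Gut Microbiome Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking the breast milk microbiome to the infant gut
    microbiome in mother-infant dyads sampled longitudinally. Implements
    generalized UniFrac beta diversity on a shared phylogeny, enterotype-style
    microbiome typing by partitioning around medoids with gap-statistic
    diagnostics, a dyad read-overlap statistic with a random-pairing null and
    Kolmogorov-Smirnov comparison, longitudinal cluster-stability scoring,
    and cross-compartment association via exact contingency tests, (partial)
    Mantel tests and filtered taxa-taxa Spearman correlation screens. Ships a
    synthetic mother-infant cohort generator with tunable milk-to-stool
    transfer so every stage can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    jsonlite,
    lme4,
    lmerTest,
    nnet,
    stats,
    utils,
    vegan,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
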