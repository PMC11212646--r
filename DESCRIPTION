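Package: diallelpart
Title: Full-Diallel Combining Ability Analysis with Maternal and
    Reciprocal Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Griffing Method 1 (Model I) analysis of replicated full
    diallel trials: general and specific combining ability estimation,
    the combining-ability analysis of variance with the reciprocal sum
    of squares split into maternal and non-maternal components, and a
    modified partition of each parent's GCA into female-side and
    male-side components from which maternal effects are derived.
    Specific combining ability is likewise partitioned into straight
    and reciprocal cross components yielding directional reciprocal
    effects. Includes method-of-moments variance components, broad- and
    narrow-sense heritability, Baker's ratio, mid- and better-parent
    heterosis, correlations between combining-ability effects and
    hybrid performance, and a seedable diallel simulator for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
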