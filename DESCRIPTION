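Package: plumagescore
Title: Drivers of Avian Visual Attractiveness from Plumage Colour and Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from plumage illustrations and crowd ratings to
    drivers of avian visual attractiveness. Quantifies plumage colour in CIELAB
    space on a binned three-dimensional grid (colour loci), aggregates loci to
    named colour categories with light and dark forms, and derives colour
    diversity (occupied loci) and colour elaboration (mean distance from the
    global average colour). Estimates consensus attractiveness scores from raw
    1-10 crowd ratings with a mixed model adjusting for photo quality and rater
    language, prepares predictor tables (log transforms, z-scaling, residual
    ornament allometry, categorical reclassification, collinearity screening),
    and fits beta generalized linear mixed models with nested taxonomic random
    intercepts by Laplace approximation. A synthetic-data module generates
    taxonomies, plumage images, trait tables and rating tables with known
    ground truth so every stage has an exact-recovery or parameter-recovery
    test without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    lme4,
    farver,
    tibble,
    dplyr,
    tidyr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
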