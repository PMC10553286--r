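Package: eatrhythm
Title: Eating Regularity, Infant Sleep, and Gut Microbiota Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies day-to-day regularity of infant meal timing with the
    Eating Regularity Index (ERI): binary 15-min epoch meal-start profiles are
    smoothed with a double circular simple moving average and compared across
    all day pairs by cosine similarity. Couples the index to actigraphy-derived
    sleep composites through multilevel models with AIC/BIC random-structure
    selection, per-age linear models, and one-way ANOVA age trends, and tests
    whether gut-microbiota maturation markers (alpha diversity, a random-forest
    bacterial maturation index, enterotypes, phylum abundances) mediate the
    eating-sleep association via the Baron-Kenny causal-steps procedure. A
    built-in synthetic cohort generator with known ground truth makes every
    stage testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    vegan,
    cluster,
    randomForest,
    lme4,
    lmerTest,
    phyloseq
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
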