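Package: gcmicro
Title: Developmental Glucocorticoid Windows and Offspring Gut Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how maternal glucocorticoid exposure during
    early gestation, late gestation, and lactation associates with offspring
    gut bacterial diversity, composition, and predicted function. Implements
    developmental-window covariate construction, alpha-diversity estimation
    (observed richness, ACE, Shannon, inverse Simpson, Faith's phylogenetic
    diversity) with mixed-effects modelling, a sampling-fraction
    bias-corrected differential-abundance engine with Benjamini-Hochberg
    control, age-moderation (simple-slopes) classification of predictor
    effects with relevance binning, Firmicutes/Bacteroidota ratio models
    with single-term-deletion likelihood-ratio tests, and a seeded
    synthetic-cohort generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    lme4,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
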