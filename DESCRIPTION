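Package: dietvae
Title: Guideline-Aligned Diet Recommendation with a Variational Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates personalized daily and weekly meal plans from user
    profiles (anthropometrics, activity level, disease flags) with a
    variational autoencoder whose recurrent decoder emits one meal per daily
    slot (breakfast to supper). Training couples the usual VAE objectives
    (reconstruction cross-entropy over meal classes, Kullback-Leibler
    regularization of the latent space) with nutrition-guideline losses that
    penalize deviations from the user's target energy intake and from
    EFSA/WHO macronutrient ranges. A portion optimizer rescales meal
    quantities so plan energy matches the target exactly, and a weekly
    masking scheme enforces meal variety. Includes a synthetic cohort and
    meal-database generator for fully reproducible experiments, a training
    loop with hand-written reverse-mode gradients, evaluation metrics
    (caloric difference, macronutrient accuracy, weekly variability, latent
    cluster separation), and an offline mock of the LLM-based
    equivalent-meal database expansion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    yaml,
    jsonlite,
    rlang,
    cluster
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
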