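Package: gpdecay
Title: Decay Curves for Genomic Prediction Accuracy over Genetic Distance
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to estimate how the accuracy of genomic prediction of
    quantitative traits (measured as the Pearson correlation between
    predicted and observed phenotypes) decays with the genetic distance
    between the training and target populations. Genetic distance is
    measured as F_ST, estimated by maximum likelihood under a
    Beta-Binomial (Balding-Nichols) model with the training subsample as
    the ancestral reference. Minimally related training/target splits are
    produced by k-means clustering on standardized allele counts, and a
    swap-resampling scheme generates pairs of subsamples at decreasing
    genetic distance; local regression (LOESS) and a linear approximation
    summarise the resulting decay curve. Includes an elastic-net genomic
    prediction front end tuned by cross-validated predictive correlation,
    a forward-in-time breeding-program simulator (random mating with
    recombination, additive traits, truncation selection) and a
    Balding-Nichols synthetic-population generator so that every stage
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
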