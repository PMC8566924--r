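Package: cultivopt
Title: Surrogate Modelling and Evolutionary Optimization of In Vitro Plant Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models in vitro plant tissue-culture growth responses to light
    spectrum (blue, red, white, far-red irradiance) and sucrose supply with
    three surrogate model families: a generalized regression neural network
    (GRNN), a single-hidden-layer perceptron trained by Levenberg-Marquardt,
    and a Takagi-Sugeno adaptive neuro-fuzzy inference system (ANFIS).
    Includes a 66-treatment Cannabis micropropagation dataset, Box-Cox
    target normalization, repeated k-fold cross-validation with R2/RMSE/MBE
    performance indices, variable-sensitivity-ratio input ranking, and four
    bound-constrained evolutionary optimizers (genetic algorithm,
    biogeography-based optimization, interior search, symbiotic organisms
    search) for locating growth-maximizing culture conditions on a fitted
    surrogate, plus a seeded synthetic response-surface generator for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
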