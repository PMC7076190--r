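Package: dinapg
Title: Bayesian Estimation of the DINA Model via Polya-Gamma Gibbs Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully Bayesian estimation of the reparameterized DINA
    (deterministic inputs, noisy "and" gate) cognitive-diagnosis model.
    A Polya-Gamma data-augmentation Gibbs sampler draws the item intercept
    and interaction parameters from closed-form Gaussian and truncated
    Gaussian conditionals, with latent attribute classes and class-membership
    probabilities updated by multinomial and Dirichlet steps. Includes a
    random-walk Metropolis-Hastings baseline, Q-matrix identifiability
    checks (completeness, attribute counts, distinct submatrix columns),
    Gelman-Rubin convergence diagnostics, posterior summaries (EAP, SD,
    highest posterior density intervals), and a simulation engine with
    bias/MSE and attribute-classification accuracy metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
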