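Package: esfm
Title: Enhanced-Sampling Force Matching for Coarse-Grained Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and exploiting the invariance of the conditional
    mean force under biases applied along coarse-grained (CG) coordinates.
    Provides analytic model systems (Muller-Brown surface, one-dimensional
    double well, a four-bead dihedral chain) with exact quadrature oracles for
    the potential of mean force, mean force and marginal density; overdamped
    Langevin samplers with umbrella, Gaussian-restraint and well-tempered
    metadynamics biases; recomputation of unbiased forces and importance
    weights on biased trajectories; nonparametric binned mean-force and
    self-normalized reweighting estimators; and a radial-basis-function neural
    network CG potential trained by variational force matching, with
    conservative forces by construction. Includes evaluation metrics
    (mean-force RMSE, histogram free energies, KL divergence, stability
    counts), CG Langevin simulation with trained potentials, and an experiment
    driver with reproducible text-based serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
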