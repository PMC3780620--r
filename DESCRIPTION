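Package: numbayes
Title: Bayesian Nonparametric Ideal-Observer Models of Numerosity Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how unsupervised category learning shapes
    perceptual number estimation. Implements a Chinese restaurant process
    mixture ideal observer with conjugate normal-inverse-gamma count
    predictives and Dirichlet-multinomial color predictives, exact
    partition enumeration for small problems, a Rao-Blackwellized
    particle filter for full sessions, per-subject maximum-likelihood
    fitting of the rational observer and its exemplar (all-singletons)
    limit with BIC-based model comparison, generators for interleaved
    two-category estimation experiments, and the standard behavioral
    statistics battery (condition means, paired t-tests, Cohen's d,
    Fisher-z sequential correlations, Wilcoxon signed-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
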