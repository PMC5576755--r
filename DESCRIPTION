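Package: phyloperturb
Title: Tree-Aware Multivariate Analysis of Longitudinal Microbiome
    Perturbation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for longitudinal microbiome perturbation experiments
    in which a dense sampling schedule brackets a single disturbance day.
    Provides phylogenetically informed ordination (generalized PCA, double
    principal coordinates analysis, and an adaptive interpolation between
    them whose tree-prior strength is estimated from the data by marginal
    likelihood), sparse discriminant analysis on combined leaf and
    internal-node features of the phylogeny, sparse canonical correlation
    analysis by penalized matrix decomposition for coupling taxon abundances
    with gene-function abundances, a windowed Shannon-diversity resilience
    statistic with elastic-net prediction from baseline composition, and a
    power study comparing crossover and parallel designs under a
    random-intercept model. A synthetic-study generator reproduces the
    statistical structure these analyses assume so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    broom,
    dplyr,
    ggplot2,
    glmnet,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    biomformat,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
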