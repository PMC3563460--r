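Package: gsbench
Title: Benchmarking Statistical Methods for Genomic Prediction in
    Heterogeneous-Stock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale benchmark of statistical methods for genomic
    selection: ridge-regression SNP-BLUP (direct, SVD and Gauss-Seidel
    residual-update solvers), two-stage subset selection, LASSO, Bayesian
    mixture regression (BayesC and BayesCpi via Gibbs sampling, a
    spike-and-Laplace model fitted by variational EM), reproducing-kernel
    Hilbert space regression with a Gaussian kernel, support vector
    regression, random forests and a pedigree-only polygenic baseline.
    Includes a gene-dropping simulator of admixed multi-founder populations
    with high linkage disequilibrium and full-sib family structure, pedigree
    EM-REML with a cage effect, phenotype pre-adjustment, within- and
    across-family cross-validation, evaluation statistics (predictive
    ability, bias, inflation, NRMSE), expected accuracy from population
    parameters, and a genetic-group accuracy analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    glmnet,
    e1071,
    ranger
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
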