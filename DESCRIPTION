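Package: shellpop
Title: Marker-Panel Power, Fine-Scale Population Structure and Shell
    Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the resolution of microsatellite and SNP
    marker panels on fine-scale population structure, coupled with outline
    morphometrics and shell pigmentation analysis. Implements Weir-Cockerham
    F_ST with permutation significance, a Markov-chain exact test of
    Hardy-Weinberg proportions, Storey q-values, ddRAD SNP filtering rules,
    drift-based power simulation in the style of POWSIM, elliptic Fourier
    outline analysis with generalized Procrustes superimposition and
    thin-plate-spline deformation grids, a shell colour index, and
    random-intercept genotype-phenotype association models. A synthetic-data
    module generates genotypes, shell outlines and pigmentation images with
    known structure so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
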