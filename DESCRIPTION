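Package: cordmetab
Title: Cord Versus Adult Plasma Metabolomics Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for untargeted plasma metabolomics screens
    that compare umbilical cord plasma with adult age groups. Implements
    feature quality control (retention-time and prevalence filters, outlier
    sample removal, per-batch median normalization), rule-based compound
    annotation with composite identification scores, differential abundance
    and age-correlation statistics with a two-step antiaging candidate
    filter, quadrant grouping and composite ranking, a lasso-regularized
    partial-correlation network with EBIC model selection and weighted
    centralities, pathway enrichment (quantitative global test,
    over-representation, topology impact, group activity), PCA and classical
    MDS ordination, and a seeded synthetic cohort generator with ground-truth
    labels for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
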