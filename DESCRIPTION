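Package: brainstates
Title: Dynamic Brain-State Analysis of Parcellated rs-fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits K-state multivariate-Gaussian hidden Markov models to
    concatenated, standardized, parcellated resting-state fMRI time series and
    extracts the temporal statistics used in dynamic brain-state studies:
    fractional occupancy, averaged lifetime, switching rate, and per-subject
    transition matrices. Includes variational-Bayes model inversion with
    free-energy tracking, occupancy-based model-order selection over a sweep of
    state counts, state characterization by mean activity and functional
    connectivity (with resting-state-network block summaries), and a group
    inference battery (rank-based inverse normal transform, fixed-effect linear
    models with age and sex covariates, Tukey post-hoc contrasts, Bonferroni
    correction per temporal feature, bootstrap Cohen's d, and severity
    correlations). A synthetic-cohort generator with known ground-truth Markov
    dynamics supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    data.table,
    emmeans
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
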