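Package: pdcnet
Title: Effective Connectivity, Directed Graph Metrics and Severity
    Classification for Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end analysis of multichannel resting-state EEG for
    grading social-anxiety severity. Fits multivariate autoregressive
    (MVAR) models per epoch, derives partial directed coherence (PDC)
    spectra and band-averaged directed connectomes, thresholds them by
    global cost efficiency, computes directed graph-theory measures
    (degree, strength, clustering, local efficiency, modularity), and
    classifies four severity groups with cross-validated machine
    learning. Includes a synthetic-cohort generator with known directed
    coupling ground truth and SIAS symptom scores, minimal European Data
    Format (EDF) input/output, Welch band-power analysis, one-way ANOVA
    with effect sizes, and Pearson symptom-severity correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    igraph,
    e1071,
    MASS,
    class,
    rpart,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
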