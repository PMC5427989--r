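Package: twinewas
Title: Twin-Design Epigenome-Wide Association Pipeline for Chronic Widespread Pain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for bin-level methylation analysis in twin cohorts:
    longitudinal-stability filtering of 500 bp methylation bins, discovery of
    differentially methylated bins in disease-discordant monozygotic pairs with
    independent replication and direction-concordant Fisher combination,
    effective-number-of-tests correction from eigenvalues of the bin
    correlation matrix, covariate logistic models, and maximum-likelihood
    liability-threshold variance decomposition separating additive-genetic,
    epigenetic and residual components of liability to a binary trait.
    Includes a synthetic twin-cohort generator with ACE bin structure,
    longitudinal repeat visits, zero inflation and a liability-threshold
    disease model, used for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
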