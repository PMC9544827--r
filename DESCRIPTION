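Package: screenmin
Title: Two-Stage Multiple Testing of Union Hypotheses by Screening Minimum P-Values
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-stage familywise-error-rate procedures for testing many
    union (partial conjunction) hypotheses, each formed from a pair of
    component p-values, as arise in high-dimensional mediation screening
    and replicability analysis. Hypothesis pairs are screened on the
    minimum p-value and survivors are tested on the maximum p-value.
    Implements the fixed-threshold procedure with Bonferroni testing of
    survivors, the adaptive single-threshold variant, per-family error
    rate estimation and control, and the max-p Bonferroni baseline;
    exact finite-sample machinery under a Gaussian mean-shift mixture
    model (conditional p-value distributions after selection, the
    familywise error rate bound, power, and oracle selection-threshold
    solvers); and a Monte-Carlo harness for type-I-error and power
    studies under independent or equicorrelated test statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
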