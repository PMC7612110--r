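Package: grapherr
Title: Graphical Multiple Testing with Generalized Error Rates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Graphical multiple comparison procedures for structured families
    of hypotheses, extended beyond familywise error rate (FWER) control to
    generalized error rates: the k-FWER (probability of k or more false
    rejections), the tail probability of the false discovery proportion
    (FDP), and derived false discovery rate (FDR) bounds.  Hypothesis graphs
    are weighted directed graphs whose node weights are local significance
    level fractions and whose edges propagate the level of rejected
    hypotheses.  Provides the Bonferroni-based graphical shortcut with
    adjusted p-values, augmented and generalized graphical procedures for
    k-FWER and FDP control, entangled (multi-graph) procedures including an
    r-of-n gatekeeper builder, weighted parametric (min-p) tests under a
    known multivariate normal dependence, and a trial simulator for
    estimating operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml, mvtnorm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
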