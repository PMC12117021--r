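Package: neglectdisc
Title: Lesion-Network and Disconnection Mapping of Spatial Neglect After
    Subcortical Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying spatial neglect after subcortical
    stroke through indirect estimates of brain disconnection. Implements
    centre-of-cancellation scoring of cancellation tests, lesion-network
    mapping from a normative resting-state connectome (seed correlation,
    Fisher z averaging, cortical masking), voxel-wise frequentist mapping
    with maximum-statistic permutation family-wise error correction,
    Bayes-factor evidence mapping with conventional evidence bins,
    streamline-level structural disconnection with prevalence filtering and
    one-tailed permutation inference, tract-wise lesion load from
    probabilistic tract atlases with rank-correlation statistics, and
    random-forest classification of neglect with a permutation test of the
    cross-validated AUC. Ships a synthetic-cohort generator with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
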