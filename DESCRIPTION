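Package: synthbias
Title: Controlled In Silico Trials of Morphological Bias in Neuroimaging AI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates counterfactual synthetic 3D neuroimage datasets with
    known, localized disease and bias deformation effects sampled from PCA
    models over stationary velocity fields (Log-Euclidean framework), trains
    an identical 3D convolutional neural network classifier across bias
    scenarios, applies three bias-mitigation strategies (reweighing,
    adversarial unlearning, per-group models), and quantifies subgroup
    performance disparities and saliency-based bias localization (SmoothGrad
    with region-wise weighted saliency scores).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite,
    digest
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
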