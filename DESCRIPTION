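Package: lesiongan
Title: Adversarial Synthesis of Paired Brain-Tumor MRI Slices by Label Compositing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Augments multi-modal brain MRI segmentation datasets by
    compositing the tumor region of one patient onto the brain background of
    another and training a conditional generative adversarial network to
    render the composite label into a realistic image. Provides the composite
    label construction with admissibility checks, the residual encoder-decoder
    generator and paired local/global patch discriminators, regional
    perceptual and regional L1 losses alongside a least-squares adversarial
    objective, a CPU training loop with full determinism, a synthetic phantom
    generator emulating skull-stripped multi-modal slices for testing, and
    Dice / Frechet-distance evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    EBImage,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
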