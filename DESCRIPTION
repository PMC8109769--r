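Package: sganweeds
Title: Semi-Supervised GAN for Crop/Weed Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised generative adversarial network (SGAN) for
    two-class crop/weed discrimination in RGB field imagery with few labels.
    A DCGAN-style generator provides synthetic images while a (K+1)-class
    fully convolutional discriminator doubles as the crop/weed classifier;
    the discriminator minimises a combined supervised/unsupervised loss and
    the generator is trained by feature matching. Includes a procedural
    generator of labelled crop/weed field images, a labeled-rate experiment
    harness comparing semi-supervised (SSCA) against supervised (SCA)
    classification accuracy, and a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
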