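Package: cutct
Title: Contrastive Unpaired CBCT-to-Synthetic-CT Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unpaired translation of cone-beam CT (CBCT) volumes into
    fan-beam-quality synthetic CT using contrastive unpaired translation
    (CUT): a ResNet generator, a 70x70 patch discriminator and a multi-layer
    patch-wise noise-contrastive (PatchNCE) objective, trained on axial 2-D
    slices. Includes the full preprocessing chain (HU clipping, resampling,
    Otsu body masking with couch removal, three-segment Hounsfield-unit
    channel encoding), image-quality evaluation (MAE, RMSE, global SSIM,
    Frechet inception distance, cross-validation fold summaries), and a
    seeded pelvic phantom simulator that provides aligned ground truth for
    end-to-end testing. Networks and their training loop are implemented
    natively with Rcpp GEMM convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
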