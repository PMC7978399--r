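Package: sucgan
Title: Synthetic CT Generation from Single-Channel MR with a Shallow U-Net
    Conditional GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-modality medical image translation from a single
    T2-weighted MR channel to synthetic CT in Hounsfield Units, using a
    conditional generative adversarial network whose generator is a
    shallow (depth-2) U-Net, together with the conventional depth-3 U-Net
    benchmark generator, an L1-regularised adversarial training protocol,
    leave-one-out experiment orchestration, image-quality evaluation
    metrics (MAPE, RMSE, PSNR, global SSIM) with per-structure analysis,
    and a seed-reproducible digital pelvis phantom simulator that provides
    paired MR/CT cohorts with contoured structures for training and
    validation at desk scale. Networks are built from declarative
    architecture specifications and parameters are counted exactly; tensor
    operations run on plain R arrays through BLAS matrix products with two
    small compiled patch-gather/scatter kernels, so no deep-learning
    runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
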