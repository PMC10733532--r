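Package: naunet
Title: Neighbored-Attention U-Net for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and profiles the neighbored-attention U-Net
    (NAU-Net), an encoder-decoder segmentation network for retinal blood
    vessels in fundus photographs, together with its attention U-Net and
    U-Net++ baselines. Encoder feature maps of neighboring resolution levels
    are fused by up-convolution and concatenation, then gated against the
    decoder feature map of the same level by a learned additive attention
    gate. Includes the compound binary cross-entropy/soft-Dice training loss,
    per-image Dice/IoU/accuracy/precision evaluation, a static complexity
    profiler (parameters, activation memory, FLOPs, MAdds), readers for the
    DRIVE, HRF and CHASE_DB1 dataset layouts, and a seeded synthetic-fundus
    generator so the full pipeline runs without external data. All network
    layers, the reverse-mode gradient tape, the Adam optimizer and the
    cosine-annealing schedule are implemented in the package with
    Rcpp/RcppArmadillo compute kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
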