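Package: painflow
Title: Facial Pain Intensity Recognition from Motion Features with Supervised pLSA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Recognizes graded facial pain expression (no pain, slight,
    moderate, severe) from grayscale image sequences. Dense per-pixel
    velocity is estimated between consecutive frames with an iterative
    Horn-Schunck scheme, half-wave rectified into four nonnegative motion
    channels, Gaussian-blurred and normalized. Frames are tiled into
    blocks, block descriptors are quantized against a k-means codebook of
    visual words, and each frame becomes a bag-of-words histogram. A
    supervised probabilistic latent semantic analysis (pLSA) topic model,
    whose latent topics are identified with the pain classes through a
    label-informed initialization, is fitted by EM; new images are
    classified by fold-in inference and posterior argmax. Includes a
    synthetic labeled dataset generator with parameterized facial-motion
    fields, an end-to-end repeated-split evaluation pipeline with
    confusion matrices, and hyperparameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
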