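Package: cycloscope
Title: Annotation-Free Cell-Cycle Manifolds from Single-Channel Live-Cell Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a spatio-temporal manifold of the cell life cycle from
    single-channel (e.g. PCNA) live-cell image trajectories without stage
    annotations. A VAE-GAN (variational autoencoder with an adversarial
    decoder and a learned-similarity reconstruction metric) is trained in
    three stages -- reconstruction warm-up, KL-weight annealing, and
    temporal cycle-consistency fine-tuning -- to embed each frame as a
    low-dimensional Gaussian posterior. Downstream tools cluster the latent
    space with Gaussian mixtures to call cell-cycle stages (with a post hoc
    G1-G2 temporal constraint), detect key-stage peaks and troughs on
    projected single-cell trajectories, and estimate cell-cycle duration
    from the projection's periodicity. A synthetic nucleus-movie generator
    with known phase, stage labels and period makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    mclust,
    zoo,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
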