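Package: mercl
Title: Multimodal Emotion Recognition with Contrastive Learning and
    Cross-Modal Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a three-modality (video, audio, EEG) emotion
    recognition framework built on supervised multimodal contrastive
    learning. Raw trials are segmented into aligned 4 s blocks; EEG blocks
    are summarised as five-band power spectral densities and audio blocks
    as 20-bin log-Mel spectrograms. Pluggable spatial encoders feed a
    residual temporal convolutional network, and the resulting
    representations are aligned in a shared embedding space by a
    three-part contrastive objective (intra-modal, inter-modal and
    sample-wise alignment terms) with audio-energy-based sample exclusion.
    A pairwise cross-modal multi-head attention stage fuses the three
    modalities for an MLP classifier, trained in a two-stage
    pre-train/fine-tune procedure with stratified fourfold
    cross-validation. Includes a seeded synthetic three-modality data
    generator so the full pipeline is testable without restricted
    benchmark datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    generics,
    ggplot2,
    jsonlite,
    signal,
    stats,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
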