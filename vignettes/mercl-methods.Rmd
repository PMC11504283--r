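---
title: "Multimodal contrastive learning for emotion recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal contrastive learning for emotion recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mercl` implements a three-modality (video, audio, EEG) emotion-recognition
framework built around supervised multimodal contrastive learning and
pairwise cross-modal attention. This vignette explains the model, its
assumptions, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate, and the
design decisions taken where the method left genuine freedom.

## The pipeline at a glance

1. **Preprocessing.** Each trial (one stimulus/response recording) is cut
   into 4 s blocks with 50% overlap, temporally aligned across the three
   modalities. EEG blocks are summarised as per-channel band powers in the
   five canonical bands — delta (0.4–4 Hz), theta (4–8 Hz), alpha (8–13 Hz),
   beta (13–30 Hz), gamma (30–45 Hz). Audio blocks become log-Mel
   spectrograms (50 ms Hamming window, 10 ms hop, 20 Mel filters). Video
   enters as a per-frame feature sequence.
2. **Encoding.** A pluggable *spatial encoder* per modality maps the
   preprocessed block to a `T x D_m` feature sequence; a shared-architecture
   *residual temporal convolutional network* (TCN) per modality then
   produces `T x D` spatiotemporal representations `h_v, h_a, h_e`.
3. **Contrastive pre-training (stage 1).** Representations are mean-pooled
   over time, linearly projected to a shared space and L2-normalized. Three
   supervised contrastive terms are minimised jointly:
   an intra-modal term (AMCL), an inter-modal term (EMCL) and a sample-wise
   alignment term (SMCL), combined as
   `L = lambda1 * L_AMCL + lambda2 * L_EMCL + lambda3 * L_SMCL`.
4. **Fusion and classification (stage 2).** With encoders frozen, six
   directed cross-modal multi-head attention blocks (`a→v, v→a, e→v, v→e,
   e→a, a→e`; queries from the direction's target, keys/values from its
   source) are pooled over query time, concatenated to a `6D` vector and fed
   to a one-hidden-layer MLP with softmax, trained with cross-entropy.
5. **Evaluation.** Stratified fourfold cross-validation at *trial* level,
   reporting accuracy and macro-averaged one-vs-rest F1.

## The contrastive objective

All terms operate on L2-normalized embeddings, so inner products are cosine
similarities in `[-1, 1]`.

**AMCL** (intra-modal): for an anchor embedding `a` in modality `m`,
positives are same-class embeddings of *other* samples in `m`, negatives are
different-class embeddings in `m`. The per-anchor loss is the negative log
ratio of summed anchor–positive similarities over the sum across positives
and negatives.

**EMCL** (inter-modal): identical functional form, but positives and
negatives are drawn from the two non-anchor modalities (hence `2N`
positives and `2M` negatives for per-modality counts `N`, `M`).

**SMCL** (sample-wise alignment): only positives — the anchor's own sample
in the other two modalities — with loss `0.5 * sum_i (s_i - alpha)^2`. The
*modality margin* `alpha` is the target cross-modal similarity; driving
similarities to `alpha` rather than 1 aligns modalities while leaving room
for modality-specific information. Because audio can be genuinely absent
(silent scenes), samples whose audio energy is flagged low/absent are
removed from every contrastive set before construction, and an audio-anchored
loss skips such anchors entirely (skips are counted and logged, never
errors).

### The softened ratio and `literal_mode`

Taken literally, a ratio of raw summed inner products can be nonpositive
(similarities can be negative), making its logarithm undefined. The default
*softened* mode therefore enters each similarity as `exp(s / temperature)`
(temperature 0.1), preserving the ratio structure while guaranteeing a
finite, nonnegative loss; it is computed with log-sum-exp for stability.
`literal_mode = TRUE` evaluates the raw-product form and raises an explicit
domain error (pointing to the softened mode) when the numerator or
denominator is nonpositive. Gradient-based training uses the softened form.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| `lambda1, lambda2, lambda3` | 1, 1, 1 | equal weighting; no term is privileged a priori |
| `alpha` | 0.8 | high alignment with slack for modality-specific structure on unit-norm embeddings |
| `temperature` | 0.1 | standard softmax-contrastive scale for cosine similarities |
| projection width `P` | 64 | shared space half the encoder width; bias-free linear map |
| temporal pooling | mean | unbiased summary of a block; `last`/`max` available |
| embedding normalization | on | makes similarities cosines and bounds the loss surface |

## The residual TCN

Each of the four blocks applies a dilated causal convolution
(`F(t) = sum_{i=0}^{k-1} f(i) x(t - d i)`, zero-padded so time `t` depends
only on `t' <= t`), batch normalization, ELU, dropout (rate 0.5) and a
residual connection; a 1x1 linear shortcut reconciles widths when a block
changes the channel count. Dilations increase as 1, 2, 4, 8, giving a
receptive field of `1 + convs_per_block * (k - 1) * (1 + 2 + 4 + 8)` — 31
steps for the default kernel size `k = 3` with one convolution per block.
Kernel size and one-vs-two convolutions per block are configurable; the
defaults (3, one) follow the block description of the method.

Numerical notes: in evaluation mode the network is deterministic — dropout
is disabled and normalization uses running statistics (initialised to
mean 0 / variance 1, momentum 0.1). Causality holds exactly in evaluation
mode; in training mode batch statistics couple time steps through the
normalization, which is standard behaviour for batch norm on sequences. For
a batch of one sample the `(B*T)`-row normalization still has `T` rows of
statistics, so tiny batches remain well-defined.

## Spatial encoders: a pluggable contract

The published system uses large pre-trained spatial encoders (a vision
transformer for frames, an audio CNN for spectrograms, a
convolution-only Conformer variant for EEG). Those weights are out of scope
here; what the package implements is the *contract*: any function mapping a
preprocessed block to a `T x D_m` matrix with a declared width can be
registered per modality (`register_spatial_encoder()`), and published
encoders can attach through it. Three small frozen reference encoders ship
for testing:

* video: identity/subsampling on precomputed frame features (16 frames per
  block by default);
* audio: contiguous segment means of the log-Mel spectrogram (16 steps),
  mirroring the coarse temporal granularity of pre-trained audio CNN
  embeddings;
* EEG: a fixed, seeded convolution over the channel axis of the
  (channels x 5 bands) PSD matrix with ELU and global channel pooling,
  tiled to 8 time steps — a stand-in for a self-attention-free Conformer.
  Band powers are `log1p`-compressed first for scale stability.

The reference encoders are deliberately frozen (like pre-trained models);
stage-1 training optimises the TCNs and projections, which is exactly the
`theta_encoder` of the two-stage procedure. Setting
`freeze_encoders = FALSE` in stage 2 additionally fine-tunes the TCNs
end-to-end; the default keeps them frozen, following the algorithm
description (the surrounding prose suggests end-to-end optimisation, so both
behaviours are exposed behind the flag).

## Cross-modal attention

Each direction is standard multi-head attention: per head, queries, keys
and values are linear projections; attention weights are the row-softmax of
`Q K^T / sqrt(d_k)`; head outputs are concatenated and mapped by `W_O`. The
method text describes the scaled dot products themselves as attention
weights without a softmax; since it invokes multi-head attention by name,
the softmax is applied by default and a `raw_scores` flag reproduces the
literal scaled-dot-product variant for study. Defaults: 4 heads,
`d_k = D / 4`, independent parameters per direction (six blocks). Each
direction's output is mean-pooled over query time before concatenation
(the time axes differ across modalities, and the description concatenates
*vectors*); `last`-step pooling is available.

## Two-stage training

Both stages use Adam (learning rates 1e-3 / 1e-4, batch size 32) and are
deterministic given the configuration seed and a fixed thread count. All
forward *and* backward passes are written in plain linear algebra inside the
package and verified against central finite differences in the test suite;
no deep-learning framework is involved. Divergence (a non-finite loss)
aborts with a diagnostic naming the offending term. Loss terms and per-term
skip counts are logged per epoch, exposed via `tidy()` and optionally
appended as JSON lines to a diagnostics file (`log_file`).

Epoch defaults (10 pre-training, 30 fine-tuning) were chosen from the loss
curves on the default synthetic benchmark, where both stages plateau well
before these limits.

## Cross-validation and metrics

Folds are assigned to whole trials (stratified by class, seeded); because
consecutive blocks overlap by 50%, block-level folds would leak near-identical
windows between train and test. Within a class the fold labels are balanced,
and remainders rotate across classes so overall fold sizes stay balanced.
The subject-level split variant does not apply to the synthetic benchmark
(it has no subject structure); trial-level is the default unit.

Accuracy is `(TP + TN) / (TP + TN + FP + FN)` and F1 is
`2 TP / (2 TP + FP + FN)` on one-vs-rest confusion counts. The binary F1 is
extended to the multiclass setting by macro-averaging over classes, with the
convention that a class with `TP = FP = FN = 0` contributes F1 = 0 and is
flagged. Reported cross-validation numbers are arithmetic means over folds.

The audio-energy threshold is computed once over all blocks (it is
label-free preprocessing), so fold splits do not change which blocks count
as silent.

## Audio-energy selection

A block's energy is the sum of squared samples. In `absolute` mode the
cutoff is given directly. The default `percentile` mode is designed to
separate "low or absent" audio from substantive audio even when silent
blocks are common: the batch's *reference energy* is the 5th percentile of
the detectable blocks (those within 60 dB of the batch maximum — digital
silence must not drag the reference down), and a block counts as absent when
its energy falls below `rel_floor = 1e-3` (30 dB) of that reference. A plain
batch percentile cannot do this job: with, say, 25% silent blocks, the 5th
percentile of the pooled energies lies *inside* the silent cluster and any
interpolated percentile of the loud cluster exceeds some loud blocks, so
neither excludes exactly the silent ones. All three knobs (mode, percentile,
relative floor) are exposed.

## The synthetic-data generator

The generator emulates the statistical structure the framework assumes, not
the physics of the signals. Each trial draws a latent
`z = centroid(class) + N(0, latent_sd^2)` in an 8-dimensional latent space;
class centroids are orthonormal directions scaled to norm 1.5 against a
within-class noise of SD 0.3 — clearly separated classes, as appropriate for
a recovery benchmark. Per modality, a fixed unit offset scaled by
`modality_gap` (default 0.5) shifts the latent, creating a controllable
modality gap; fixed random orthonormal-column mixing maps then produce:

* **video**: per-frame features = mixing map x latent + N(0, 0.1) per frame
  (16 fps, 16 features);
* **audio**: a sum of eight amplitude-modulated tones (200–2000 Hz, inside
  the Mel range), one per latent coordinate, amplitude a logistic map of the
  coordinate, plus low noise — so log-Mel energies encode the latent
  (16 kHz);
* **EEG**: eight channels, each a sum of five band-centred sinusoids
  (2, 6, 10.5, 21, 37 Hz) whose amplitudes encode the mixed latent, plus
  0.5 uV noise at 128 Hz — so band PSD recovers the latent.

A `silent_audio_frac` of trials (default 0.1) get Gaussian noise at 1e-4
amplitude instead of tones — near-silence rather than exact zeros, so
thresholding is exercised realistically. Defaults: 4 classes (mirroring the
four valence–arousal quadrants), 10 trials per class, 12 s per trial
(5 blocks each, 200 blocks total). The whole dataset is a deterministic
function of the spec, including its seed; the export manifest reproduces it
bit-exactly.

What the generator does **not** emulate: EEG artifacts and event-related
dynamics, 1/f spectra, real video statistics, perceptual audio realism,
subject-level variability, or label noise. Passing the recovery benchmark
therefore shows that the pipeline's mechanics (feature extraction, encoding,
contrastive alignment, fusion, training loop, evaluation protocol) are
correct and that it can exploit cross-modally shared class structure — not
that it attains any particular accuracy on real EEG datasets.

## Problem sizes used in the shipped checks

The test suite runs the formula-level checks at small dimensions
(hundreds of random instances), the alignment recovery at `B = 16, D = 32,
P = 16` for 2000 steps, and the end-to-end recovery on the default
generator (200 blocks) with the default training configuration under
fourfold cross-validation — sizes at which the full pipeline completes in a
few minutes on a single CPU while still exercising every code path at the
documented defaults.

## Known limitations

* No GPU or multi-core path; the implementation targets correctness and
  desk-scale data.
* Batch normalization in training mode couples time steps; strict causality
  is an evaluation-mode property.
* `max` fusion pooling is forward-only (no backward), so it can be used for
  inference experiments but not training.
* The container format is a flat directory (manifest + WAV + raw float64
  arrays); EDF/HDF5 readers can be attached upstream of `trial_record()`.
* Real-data questions — subject-independent splits, electrode montages,
  artifact handling — are intentionally out of scope.
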