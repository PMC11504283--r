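# Shared fixtures, built in code. Small sampling rates keep the suite fast;
# the end-to-end acceptance checks use the generator defaults.

## A cheap trial with controllable duration (rates chosen so slicing is exact).
make_trial <- function(duration_s, label = 0L, video_fps = 2, audio_fs = 100,
                       eeg_fs = 64, id = "t1") {
  n_f <- round(duration_s * video_fps)
  trial_record(video = matrix(seq_len(n_f * 3) / 10, n_f, 3),
               video_fps = video_fps,
               audio = sin(seq_len(round(duration_s * audio_fs)) / 5),
               audio_fs = audio_fs,
               eeg = matrix(stats::rnorm(2 * round(duration_s * eeg_fs)),
                            nrow = 2),
               eeg_fs = eeg_fs, label = label, trial_id = id)
}

## Small synthetic dataset for pipeline tests (shared via lazy cache).
tiny_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds))
      ds <<- generate_synth_dataset(synth_spec(
        n_trials_per_class = 4L, trial_len_s = 8, audio_fs = 8000,
        seed = 123L))
    ds
  }
})

tiny_features <- local({
  ft <- NULL
  function() {
    if (is.null(ft)) ft <<- prepare_blocks(tiny_dataset())
    ft
  }
})

## Small training configuration for pipeline tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(pretrain_epochs = 3L, finetune_epochs = 10L, seed = 42L,
         tcn = tcn_config(channels = 32L), proj_dim = 16L,
         classifier_hidden = 64L),
    list(...))
  do.call(train_config, args)
}

## Random L2-normalized embedding matrices for the three modalities.
random_embeddings <- function(B, P, seed = 1) {
  set.seed(seed)
  z <- lapply(c(video = 1, audio = 2, eeg = 3), function(i)
    matrix(stats::rnorm(B * P), B))
  lapply(z, function(m) m / sqrt(rowSums(m^2)))
}

## Direct discrete-Fourier-transform periodogram (oracle for band powers):
## power of the sinusoidal component nearest frequency f0.
dft_band_power <- function(x, fs, band) {
  n <- length(x)
  freqs <- (0:(n - 1)) * fs / n
  p <- Mod(stats::fft(x))^2 / n^2
  keep <- freqs >= band[1] & freqs <= band[2]
  2 * sum(p[keep & freqs <= fs / 2])  # one-sided
}
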