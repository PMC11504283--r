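# Preprocessing: trial segmentation into aligned blocks, EEG band power
# spectral densities, audio log-Mel spectrograms and audio-energy flags.

#' Construct a single-trial record
#'
#' A trial couples the three modality streams recorded while a subject watched
#' one stimulus: a video stream (frame-feature sequence or raw frame array),
#' the audio waveform and the multi-channel EEG recording, plus the emotion
#' label for the whole trial.
#'
#' @param video Matrix (frames x features) of per-frame features, or an array
#'   whose first dimension indexes frames.
#' @param video_fps Video frame rate (frames per second).
#' @param audio Numeric waveform, samples in `[-1, 1]`.
#' @param audio_fs Audio sampling rate in Hz.
#' @param eeg Matrix (channels x samples) in microvolts.
#' @param eeg_fs EEG sampling rate in Hz.
#' @param label Integer class id (0-based or factor level index; kept opaque).
#' @param trial_id Identifier string.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(video, video_fps, audio, audio_fs, eeg, eeg_fs,
                         label, trial_id = "trial") {
  if (is.null(dim(video))) video <- matrix(video, ncol = 1L)
  if (is.vector(eeg)) eeg <- matrix(eeg, nrow = 1L)
  for (nm in c("video_fps", "audio_fs", "eeg_fs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stopf("`%s` must be a positive rate", nm)
  }
  structure(list(video = video, video_fps = video_fps,
                 audio = as.numeric(audio), audio_fs = audio_fs,
                 eeg = eeg, eeg_fs = eeg_fs,
                 label = label, trial_id = as.character(trial_id)),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record %s> label=%s | video %d frames @%g fps | audio %.2f s @%g Hz | eeg %d ch x %.2f s @%g Hz\n",
              x$trial_id, format(x$label), nrow(x$video), x$video_fps,
              length(x$audio) / x$audio_fs, x$audio_fs,
              nrow(x$eeg), ncol(x$eeg) / x$eeg_fs, x$eeg_fs))
  invisible(x)
}

## Number of whole blocks in `duration` seconds (shared by segmentation and
## its tests' brute-force oracle).
n_blocks_for <- function(duration_s, block_len_s, hop_s) {
  if (duration_s < block_len_s) return(0L)
  as.integer(floor((duration_s - block_len_s) / hop_s + 1e-9)) + 1L
}

#' Segment a trial into temporally aligned blocks
#'
#' Cuts all three modality streams into windows of `block_len_s` seconds with
#' a hop of `block_len_s * (1 - overlap_frac)`, after applying a fixed
#' per-modality synchronization lag (the stream's first `lag_s` seconds are
#' dropped). Every block spans the same wall-clock interval in every modality
#' and inherits the trial's label.
#'
#' @param trial A [trial_record()].
#' @param block_len_s Block length in seconds (default 4).
#' @param overlap_frac Fractional overlap between consecutive blocks in
#'   `[0, 1)` (default 0.5).
#' @param lag_s Named numeric vector of per-modality lags in seconds, e.g.
#'   `c(video = 0, audio = 0, eeg = 0)`.
#' @return An object of class `block_set`: a list of blocks (each with
#'   `video`, `audio`, `eeg` slices and `start_s`), plus segmentation
#'   parameters, rates and the trial's label.
#' @export
segment_trial <- function(trial, block_len_s = 4, overlap_frac = 0.5,
                          lag_s = c(video = 0, audio = 0, eeg = 0)) {
  stopifnot(inherits(trial, "trial_record"))
  if (!is.numeric(block_len_s) || block_len_s <= 0)
    stopf("`block_len_s` must be positive")
  if (!is.numeric(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1)
    stopf("`overlap_frac` must be in [0, 1)")
  lag <- c(video = 0, audio = 0, eeg = 0)
  lag[names(lag_s)] <- lag_s
  if (any(lag < 0)) stopf("lags must be nonnegative")

  vid <- trial$video
  if (lag["video"] > 0) {
    drop <- round(lag["video"] * trial$video_fps)
    vid <- vid[-seq_len(min(drop, nrow(vid))), , drop = FALSE]
  }
  aud <- trial$audio
  if (lag["audio"] > 0) {
    drop <- round(lag["audio"] * trial$audio_fs)
    aud <- aud[-seq_len(min(drop, length(aud)))]
  }
  eeg <- trial$eeg
  if (lag["eeg"] > 0) {
    drop <- round(lag["eeg"] * trial$eeg_fs)
    eeg <- eeg[, -seq_len(min(drop, ncol(eeg))), drop = FALSE]
  }

  dur <- min(nrow(vid) / trial$video_fps,
             length(aud) / trial$audio_fs,
             ncol(eeg) / trial$eeg_fs)
  hop_s <- block_len_s * (1 - overlap_frac)
  nb <- n_blocks_for(dur, block_len_s, hop_s)
  if (nb < 1L)
    stopf("trial too short: %.3f s of aligned signal, need at least %.3f s",
          dur, block_len_s)

  slice <- function(i, rate, get_n, take) {
    start <- (i - 1L) * hop_s
    i0 <- round(start * rate) + 1L
    n <- round(block_len_s * rate)
    i1 <- min(i0 + n - 1L, get_n)
    take(i0, i1)
  }
  blocks <- lapply(seq_len(nb), function(i) {
    list(
      video = slice(i, trial$video_fps, nrow(vid),
                    function(a, b) vid[a:b, , drop = FALSE]),
      audio = slice(i, trial$audio_fs, length(aud), function(a, b) aud[a:b]),
      eeg = slice(i, trial$eeg_fs, ncol(eeg),
                  function(a, b) eeg[, a:b, drop = FALSE]),
      start_s = (i - 1L) * hop_s)
  })
  structure(list(blocks = blocks, block_len_s = block_len_s,
                 overlap_frac = overlap_frac, lag_s = lag,
                 label = trial$label, trial_id = trial$trial_id,
                 video_fps = trial$video_fps, audio_fs = trial$audio_fs,
                 eeg_fs = trial$eeg_fs),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("<block_set %s> %d blocks of %g s (%.0f%% overlap), label=%s\n",
              x$trial_id, length(x$blocks), x$block_len_s,
              100 * x$overlap_frac, format(x$label)))
  invisible(x)
}

#' Default EEG frequency bands
#'
#' The five canonical bands: delta (0.4-4 Hz), theta (4-8 Hz), alpha
#' (8-13 Hz), beta (13-30 Hz) and gamma (30-45 Hz).
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
default_band_edges <- function() {
  list(delta = c(0.4, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 45))
}

#' Per-band EEG power spectral density of one block
#'
#' Each channel is band-limited with a zero-phase Butterworth filter
#' (order `filter_order`, applied forward-backward via [signal::filtfilt()])
#' and the band's power is the mean squared amplitude of the filtered signal.
#'
#' @param eeg_block Matrix (channels x samples) or numeric vector (one
#'   channel), in microvolts.
#' @param fs Sampling rate in Hz; must exceed twice the highest band edge.
#' @param band_edges List of 5 `c(low, high)` pairs; defaults to
#'   [default_band_edges()].
#' @param filter_order Butterworth order (default 4).
#' @return Object of class `eeg_band_psd` with `psd` (channels x 5 matrix of
#'   nonnegative band powers, microvolt^2) and `band_edges`.
#' @export
eeg_band_psd <- function(eeg_block, fs, band_edges = default_band_edges(),
                         filter_order = 4L) {
  if (is.vector(eeg_block)) eeg_block <- matrix(eeg_block, nrow = 1L)
  if (anyNA(eeg_block) || !all(is.finite(eeg_block)))
    stopf("EEG block contains NaN or non-finite values")
  if (length(band_edges) != 5L)
    stopf("`band_edges` must list exactly 5 bands")
  hi <- max(vapply(band_edges, max, numeric(1)))
  lo <- min(vapply(band_edges, min, numeric(1)))
  if (fs <= 2 * hi)
    stopf("sampling rate %g Hz violates Nyquist for the %g Hz band edge", fs, hi)
  if (ncol(eeg_block) / fs < 1 / lo)
    stopf("block too short: need at least one period (%.2f s) of the lowest band",
          1 / lo)
  psd <- matrix(0, nrow(eeg_block), length(band_edges),
                dimnames = list(NULL, names(band_edges)))
  for (b in seq_along(band_edges)) {
    e <- band_edges[[b]]
    flt <- signal::butter(filter_order, c(e[1], e[2]) / (fs / 2), type = "pass")
    for (ch in seq_len(nrow(eeg_block))) {
      y <- signal::filtfilt(flt, eeg_block[ch, ])
      psd[ch, b] <- mean(y^2)
    }
  }
  structure(list(psd = psd, band_edges = band_edges, fs = fs),
            class = "eeg_band_psd")
}

## HTK-style mel scale.
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

## Triangular mel filterbank over the one-sided spectrum of an n_fft window.
mel_filterbank <- function(n_mels, n_fft, fs) {
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * fs / n_fft
  pts <- mel_to_hz(seq(0, hz_to_mel(fs / 2), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    f_lo <- pts[m]; f_c <- pts[m + 1L]; f_hi <- pts[m + 2L]
    up <- (freqs - f_lo) / max(f_c - f_lo, .Machine$double.eps)
    down <- (f_hi - freqs) / max(f_hi - f_c, .Machine$double.eps)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-Mel spectrogram of one audio block
#'
#' Applies a Hamming window (`window_ms`, default 50 ms) with a `hop_ms`
#' (default 10 ms) hop, takes the short-time Fourier transform of each
#' windowed segment, projects the power spectrum onto `n_mels` (default 20)
#' triangular Mel filters and log-compresses with an additive floor.
#'
#' @param audio_block Numeric waveform.
#' @param fs Sampling rate in Hz.
#' @param window_ms,hop_ms Analysis window length and hop in milliseconds.
#' @param n_mels Number of Mel filter banks.
#' @param log_floor Positive constant added before the logarithm.
#' @return Object of class `log_mel_spectrogram` with `lms`
#'   (frames x n_mels matrix of log-power) and the analysis parameters.
#'   Frame count is `floor((duration_ms - window_ms) / hop_ms) + 1`.
#' @export
log_mel_spectrogram <- function(audio_block, fs, window_ms = 50, hop_ms = 10,
                                n_mels = 20L, log_floor = 1e-10) {
  if (length(audio_block) == 0L) stopf("empty audio block")
  if (log_floor <= 0) stopf("`log_floor` must be positive")
  win <- round(fs * window_ms / 1000)
  hop <- round(fs * hop_ms / 1000)
  if (length(audio_block) < win)
    stopf("audio block shorter than one %g ms analysis window", window_ms)
  n_frames <- (length(audio_block) - win) %/% hop + 1L
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1L)) / (win - 1L))  # Hamming
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(audio_block[idx], nrow = win) * w
  spec <- stats::mvfft(frames)
  n_bins <- win %/% 2L + 1L
  power <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2
  fb <- mel_filterbank(n_mels, win, fs)
  lms <- t(log(fb %*% power + log_floor))
  structure(list(lms = lms, window_ms = window_ms, hop_ms = hop_ms,
                 n_mels = n_mels, log_floor = log_floor, fs = fs),
            class = "log_mel_spectrogram")
}

#' Audio energy of a waveform
#'
#' @param x Numeric waveform.
#' @return Sum of squared samples.
#' @export
audio_energy <- function(x) sum(as.numeric(x)^2)

#' Flag blocks with low or absent audio energy
#'
#' Computes each block's energy (sum of squared samples) and flags blocks
#' whose audio is effectively missing, so downstream sample-wise alignment can
#' exclude them. In `"absolute"` mode the cutoff is `threshold_value` itself.
#' In `"percentile"` mode the batch's reference energy is the
#' `threshold_value`-th percentile of the *detectable* blocks (those within
#' `detect_db` of the batch maximum, so that a mass of silent blocks cannot
#' drag the reference down), and a block is flagged absent when its energy
#' falls below `rel_floor` (default 1e-3, i.e. 30 dB) of that reference.
#'
#' @param audio_blocks List of numeric waveforms (or a `block_set`).
#' @param threshold_mode `"percentile"` (default) or `"absolute"`.
#' @param threshold_value Percentile in `[0, 100]` (default 5) or absolute
#'   energy cutoff.
#' @param rel_floor Fraction of the reference energy below which audio counts
#'   as absent (percentile mode only).
#' @param detect_db Dynamic-range cut (dB, energy scale) separating
#'   detectable blocks from digital silence when computing the reference.
#' @return A tibble with one row per block: `energy`, `is_present`,
#'   `threshold`.
#' @export
audio_energy_select <- function(audio_blocks,
                                threshold_mode = c("percentile", "absolute"),
                                threshold_value = 5,
                                rel_floor = 1e-3, detect_db = 60) {
  threshold_mode <- match.arg(threshold_mode)
  if (inherits(audio_blocks, "block_set"))
    audio_blocks <- lapply(audio_blocks$blocks, `[[`, "audio")
  if (!is.list(audio_blocks) || length(audio_blocks) == 0L)
    stopf("need at least one audio block")
  energy <- vapply(audio_blocks, audio_energy, numeric(1))
  if (threshold_mode == "absolute") {
    thr <- threshold_value
  } else {
    if (threshold_value < 0 || threshold_value > 100)
      stopf("percentile must be in [0, 100]")
    detectable <- energy > max(energy) * 10^(-detect_db / 10) & energy > 0
    if (!any(detectable)) {
      thr <- Inf  # whole batch is silent
    } else {
      ref <- stats::quantile(energy[detectable], threshold_value / 100,
                             names = FALSE, type = 7)
      thr <- rel_floor * ref
    }
  }
  tibble::tibble(energy = energy, is_present = energy >= thr, threshold = thr)
}
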