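# Synthetic three-modality dataset generator. Emulates the statistical
# structure the framework assumes -- three modality streams sharing a latent
# class structure, per-modality noise, a controllable cross-modal gap and a
# controllable fraction of silent audio -- so the whole pipeline is testable
# without restricted benchmark data. It does not emulate real EEG physiology
# (artifacts, ERPs) or perceptually realistic audio/video.

#' Specification of a synthetic three-modality dataset
#'
#' Each trial draws a latent vector `z = centroid(class) + N(0, latent_sd^2)`.
#' Per modality, a fixed offset of magnitude `modality_gap` shifts the latent
#' (the modality gap), and a fixed seeded mixing map turns the shifted latent
#' into observations: per-frame video features (linear map + noise), an audio
#' waveform of amplitude-modulated tones (one tone per latent coordinate) and
#' a multi-channel EEG signal whose per-band oscillation amplitudes encode the
#' latent -- so band PSD and log-Mel features recover class information.
#'
#' @param n_classes Number of emotion classes (default 4, mirroring the
#'   high/low valence x arousal quadrants HVHA/LVHA/LVLA/HVLA).
#' @param n_trials_per_class Trials per class (default 10).
#' @param latent_dim Width of the shared latent space (default 8).
#' @param centroid_scale Norm of each class centroid (default 1.5; centroids
#'   are orthonormal directions scaled by this, so classes are well separated
#'   relative to `latent_sd`).
#' @param latent_sd Within-class latent noise SD (default 0.3).
#' @param noise_sd Named per-modality observation noise SDs
#'   (`video` feature units, `audio` waveform units, `eeg` microvolts).
#' @param modality_gap Magnitude of the per-modality latent offset
#'   (default 0.5).
#' @param silent_audio_frac Fraction of trials whose audio is near-silent
#'   (default 0.1; "silent" is Gaussian noise at 1e-4 amplitude, not exact
#'   zeros, to exercise thresholding realistically).
#' @param trial_len_s Trial length in seconds (default 12).
#' @param video_fps,video_dim Video frame rate and per-frame feature width.
#' @param audio_fs Audio sampling rate in Hz (default 16000).
#' @param eeg_channels,eeg_fs EEG channel count and sampling rate.
#' @param seed Integer seed; the full dataset is a deterministic function of
#'   the spec (manifest reproducibility).
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_classes = 4L, n_trials_per_class = 10L,
                       latent_dim = 8L, centroid_scale = 1.5,
                       latent_sd = 0.3,
                       noise_sd = c(video = 0.1, audio = 0.005, eeg = 0.5),
                       modality_gap = 0.5, silent_audio_frac = 0.1,
                       trial_len_s = 12, video_fps = 16, video_dim = 16L,
                       audio_fs = 16000, eeg_channels = 8L, eeg_fs = 128,
                       seed = 42L) {
  check_fraction(silent_audio_frac, "silent_audio_frac")
  if (any(noise_sd < 0)) stopf("`noise_sd` must be nonnegative")
  if (modality_gap < 0) stopf("`modality_gap` must be nonnegative")
  if (n_classes < 2L) stopf("need at least 2 classes")
  if (latent_dim < n_classes)
    stopf("`latent_dim` must be >= `n_classes` for distinct centroids")
  nd <- c(video = 0.1, audio = 0.005, eeg = 0.5)
  nd[names(noise_sd)] <- noise_sd
  structure(list(n_classes = as.integer(n_classes),
                 n_trials_per_class = as.integer(n_trials_per_class),
                 latent_dim = as.integer(latent_dim),
                 centroid_scale = centroid_scale, latent_sd = latent_sd,
                 noise_sd = nd, modality_gap = modality_gap,
                 silent_audio_frac = silent_audio_frac,
                 trial_len_s = trial_len_s, video_fps = video_fps,
                 video_dim = as.integer(video_dim), audio_fs = audio_fs,
                 eeg_channels = as.integer(eeg_channels), eeg_fs = eeg_fs,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

## Matrix with orthonormal columns, drawn from the current RNG stream.
rand_orthonormal <- function(nrow, ncol) {
  qr.Q(qr(matrix(stats::rnorm(nrow * ncol), nrow, ncol)))[, seq_len(ncol),
                                                          drop = FALSE]
}

#' Generate a synthetic three-modality dataset
#'
#' @param spec A [synth_spec()].
#' @return Object of class `synth_dataset`: `trials` (list of
#'   [trial_record()]), `labels` (0-based integer classes), `silent` (logical
#'   ground-truth silent-audio flags), `latents` (trials x latent_dim),
#'   `modality_latents` (per-modality shifted latents), the fixed `mixing`
#'   maps, and the generating `spec` as manifest.
#' @export
generate_synth_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_local_seed(spec$seed, {
    L <- spec$latent_dim
    n <- spec$n_classes * spec$n_trials_per_class
    centroids <- rand_orthonormal(L, spec$n_classes) * spec$centroid_scale
    offsets <- lapply(c(video = 1, audio = 2, eeg = 3), function(i) {
      g <- stats::rnorm(L); g / sqrt(sum(g^2))
    })
    mix_video <- rand_orthonormal(spec$video_dim, L)
    mix_eeg <- rand_orthonormal(spec$eeg_channels * 5L, L)
    tone_freqs <- c(200, 350, 500, 700, 950, 1250, 1600, 2000,
                    2500, 3100, 3800, 4600)[seq_len(min(L, 12L))]
    band_centers <- c(2, 6, 10.5, 21, 37)

    labels <- rep(seq_len(spec$n_classes) - 1L, each = spec$n_trials_per_class)
    n_silent <- round(spec$silent_audio_frac * n)
    silent <- rep(FALSE, n)
    silent[sample.int(n, n_silent)] <- TRUE

    latents <- t(vapply(seq_len(n), function(i) {
      centroids[, labels[i] + 1L] + stats::rnorm(L, sd = spec$latent_sd)
    }, numeric(L)))
    mod_lat <- lapply(offsets, function(g) {
      latents + matrix(spec$modality_gap * g, n, L, byrow = TRUE)
    })

    t_aud <- seq_len(round(spec$trial_len_s * spec$audio_fs)) / spec$audio_fs
    t_eeg <- seq_len(round(spec$trial_len_s * spec$eeg_fs)) / spec$eeg_fs
    n_frames <- round(spec$trial_len_s * spec$video_fps)
    tone_mat <- sin(outer(t_aud, 2 * pi * tone_freqs))  # shared across trials

    trials <- vector("list", n)
    for (i in seq_len(n)) {
      zv <- mod_lat$video[i, ]; za <- mod_lat$audio[i, ]; ze <- mod_lat$eeg[i, ]

      video <- matrix(mix_video %*% zv, n_frames, spec$video_dim,
                      byrow = TRUE) +
        matrix(stats::rnorm(n_frames * spec$video_dim,
                            sd = spec$noise_sd["video"]),
               n_frames, spec$video_dim)

      if (silent[i]) {
        audio <- 1e-4 * stats::rnorm(length(t_aud))
      } else {
        amps <- (0.06 + 0.10 * stats::plogis(za[seq_along(tone_freqs)])) / 2
        audio <- drop(tone_mat %*% amps) +
          stats::rnorm(length(t_aud), sd = spec$noise_sd["audio"])
      }

      amp_e <- matrix(0.5 + 3 * stats::plogis(2 * (mix_eeg %*% ze)),
                      spec$eeg_channels, 5L)
      phases <- matrix(stats::runif(spec$eeg_channels * 5L, 0, 2 * pi),
                       spec$eeg_channels, 5L)
      eeg <- matrix(stats::rnorm(spec$eeg_channels * length(t_eeg),
                                 sd = spec$noise_sd["eeg"]),
                    spec$eeg_channels, length(t_eeg))
      for (b in seq_len(5L)) {
        eeg <- eeg + amp_e[, b] *
          sin(matrix(2 * pi * band_centers[b] * t_eeg,
                     spec$eeg_channels, length(t_eeg), byrow = TRUE) +
                phases[, b])
      }

      trials[[i]] <- trial_record(video, spec$video_fps, audio, spec$audio_fs,
                                  eeg, spec$eeg_fs, labels[i],
                                  sprintf("trial%03d", i))
    }
    structure(list(trials = trials, labels = labels, silent = silent,
                   latents = latents, modality_latents = mod_lat,
                   mixing = list(centroids = centroids, offsets = offsets,
                                 video = mix_video, eeg = mix_eeg,
                                 tone_freqs = tone_freqs,
                                 band_centers = band_centers),
                   spec = spec),
              class = "synth_dataset")
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d trials, %d classes, %g s each, %d silent-audio (seed %d)\n",
              length(x$trials), x$spec$n_classes, x$spec$trial_len_s,
              sum(x$silent), x$spec$seed))
  invisible(x)
}

#' Mean same-sample cross-modal cosine of generator latents
#'
#' Diagnostic for the modality-gap control: the mean (over trials and the
#' three modality pairs) cosine similarity between a trial's per-modality
#' latent vectors. Decreases as `modality_gap` grows.
#'
#' @param dataset A `synth_dataset`.
#' @return Scalar mean cosine.
#' @export
cross_modal_latent_cosine <- function(dataset) {
  ml <- dataset$modality_latents
  pairs <- list(c("video", "audio"), c("video", "eeg"), c("audio", "eeg"))
  mean(vapply(pairs, function(p) {
    a <- ml[[p[1]]]; b <- ml[[p[2]]]
    mean(rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2))))
  }, numeric(1)))
}

#' Export a synthetic dataset to a directory
#'
#' Writes a portable flat layout: `manifest.json` (spec, labels, silent flags,
#' array dimensions and file list), one IEEE-float64 WAV per trial for audio,
#' and raw little-endian float64 arrays for video features, EEG, latents and
#' mixing maps. [load_dataset()] round-trips the dataset bit-exactly.
#'
#' @param dataset A `synth_dataset`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
export_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "synth_dataset"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE)
  if (!ok) stopf("cannot create export directory '%s'", path)
  sp <- dataset$spec
  n <- length(dataset$trials)
  files <- list()
  for (i in seq_len(n)) {
    tr <- dataset$trials[[i]]
    id <- tr$trial_id
    wav <- sprintf("audio_%s.wav", id)
    vid <- sprintf("video_%s.f64", id)
    eeg <- sprintf("eeg_%s.f64", id)
    write_wav(tr$audio, file.path(path, wav), sp$audio_fs, "float64")
    write_f64(tr$video, file.path(path, vid))
    write_f64(tr$eeg, file.path(path, eeg))
    files[[id]] <- list(audio = wav, video = vid, eeg = eeg,
                        video_dim = dim(tr$video), eeg_dim = dim(tr$eeg))
  }
  write_f64(dataset$latents, file.path(path, "latents.f64"))
  for (m in names(dataset$modality_latents))
    write_f64(dataset$modality_latents[[m]],
              file.path(path, sprintf("latents_%s.f64", m)))
  write_f64(dataset$mixing$centroids, file.path(path, "mix_centroids.f64"))
  write_f64(dataset$mixing$video, file.path(path, "mix_video.f64"))
  write_f64(dataset$mixing$eeg, file.path(path, "mix_eeg.f64"))
  for (m in names(dataset$mixing$offsets))
    write_f64(dataset$mixing$offsets[[m]],
              file.path(path, sprintf("offset_%s.f64", m)))
  manifest <- list(format = "mercl-synth-v1",
                   spec = unclass(sp), labels = dataset$labels,
                   silent = dataset$silent,
                   tone_freqs = dataset$mixing$tone_freqs,
                   band_centers = dataset$mixing$band_centers,
                   trials = files)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a dataset exported by [export_dataset()]
#'
#' @param path Directory containing `manifest.json` and the stream files.
#' @return A `synth_dataset`.
#' @export
load_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stopf("no manifest.json under '%s'", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(mf$format, "mercl-synth-v1"))
    stopf("'%s': unrecognized manifest format", path)
  sp <- do.call(synth_spec, mf$spec[setdiff(names(mf$spec),
                                            character(0))])
  ids <- names(mf$trials)
  labels <- as.integer(mf$labels)
  trials <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    fi <- mf$trials[[ids[i]]]
    wav <- read_wav(file.path(path, fi$audio))
    video <- read_f64(file.path(path, fi$video), as.integer(fi$video_dim))
    eeg <- read_f64(file.path(path, fi$eeg), as.integer(fi$eeg_dim))
    trials[[i]] <- trial_record(video, sp$video_fps, wav$samples, wav$fs,
                                eeg, sp$eeg_fs, labels[i], ids[i])
  }
  L <- sp$latent_dim
  n <- length(ids)
  mod_lat <- lapply(c(video = "video", audio = "audio", eeg = "eeg"),
                    function(m) read_f64(file.path(path,
                                                   sprintf("latents_%s.f64", m)),
                                         c(n, L)))
  offsets <- lapply(c(video = "video", audio = "audio", eeg = "eeg"),
                    function(m) read_f64(file.path(path,
                                                   sprintf("offset_%s.f64", m))))
  structure(list(trials = trials, labels = labels,
                 silent = as.logical(mf$silent),
                 latents = read_f64(file.path(path, "latents.f64"), c(n, L)),
                 modality_latents = mod_lat,
                 mixing = list(
                   centroids = read_f64(file.path(path, "mix_centroids.f64"),
                                        c(L, sp$n_classes)),
                   offsets = offsets,
                   video = read_f64(file.path(path, "mix_video.f64"),
                                    c(sp$video_dim, L)),
                   eeg = read_f64(file.path(path, "mix_eeg.f64"),
                                  c(sp$eeg_channels * 5L, L)),
                   tone_freqs = mf$tone_freqs,
                   band_centers = mf$band_centers),
                 spec = sp),
            class = "synth_dataset")
}
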