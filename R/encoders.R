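# Spatial-encoder registry and the shared residual temporal convolutional
# network (TCN). Spatial encoders are pluggable: small fixed reference
# encoders ship for testing, and published pre-trained encoders can attach
# through the same contract (a function mapping preprocessed input to a
# T x D feature matrix with a declared output width).

.registry <- new.env(parent = emptyenv())

#' Register a spatial encoder for a modality
#'
#' @param modality One of `"video"`, `"audio"`, `"eeg"` (or any tag).
#' @param encoder Function mapping preprocessed modality input to a
#'   `T x width` numeric matrix of spatial features.
#' @param width Declared output feature width; `NULL` means pass-through
#'   (width inferred from the input, as for an identity encoder on
#'   precomputed features).
#' @param override Allow replacing an existing registration.
#' @return The registry entry, invisibly.
#' @export
register_spatial_encoder <- function(modality, encoder, width = NULL,
                                     override = FALSE) {
  stopifnot(is.character(modality), length(modality) == 1L,
            is.function(encoder))
  if (!override && !is.null(.registry[[modality]]))
    stopf("modality '%s' already has an encoder; use override = TRUE", modality)
  entry <- list(fn = encoder, width = width)
  assign(modality, entry, envir = .registry)
  invisible(entry)
}

#' Look up the registered spatial encoder for a modality
#'
#' @param modality Modality tag.
#' @return Registry entry with `fn` and `width`.
#' @export
spatial_encoder <- function(modality) {
  entry <- .registry[[modality]]
  if (is.null(entry))
    stopf("no encoder registered for modality '%s'", modality)
  entry
}

#' Apply the registered spatial encoder
#'
#' @param modality Modality tag.
#' @param input Preprocessed modality input.
#' @return `T x D` matrix of spatial features.
#' @export
encode_spatial <- function(modality, input) {
  entry <- spatial_encoder(modality)
  s <- entry$fn(input)
  if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
  if (!is.null(entry$width) && ncol(s) != entry$width)
    stopf("encoder for '%s' declared width %d but produced %d",
          modality, entry$width, ncol(s))
  check_finite(s, sprintf("spatial features (%s)", modality))
  s
}

## Uniform subsampling of rows to t_out steps.
subsample_rows <- function(x, t_out) {
  n <- nrow(x)
  if (n <= t_out) return(x)
  x[round(seq(1, n, length.out = t_out)), , drop = FALSE]
}

#' Reference video spatial encoder
#'
#' Stands in for a pre-trained frame-feature extractor: treats the input as a
#' precomputed frame-feature sequence and uniformly subsamples it to `t_out`
#' frames per block. Raw frame arrays (frames x H x W x C) are flattened to
#' per-frame vectors first.
#'
#' @param t_out Frames kept per block (default 16).
#' @return Encoder function for [register_spatial_encoder()].
#' @export
ref_video_encoder <- function(t_out = 16L) {
  function(x) {
    if (length(dim(x)) > 2L) x <- matrix(x, dim(x)[1])
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
    subsample_rows(x, t_out)
  }
}

#' Reference audio spatial encoder
#'
#' Stands in for a pre-trained audio CNN: pools the log-Mel spectrogram's
#' frames into `t_out` contiguous segment means, yielding a `t_out x n_mels`
#' feature sequence.
#'
#' @param t_out Output time steps per block (default 16).
#' @return Encoder function.
#' @export
ref_audio_encoder <- function(t_out = 16L) {
  function(x) {
    if (inherits(x, "log_mel_spectrogram")) x <- x$lms
    n <- nrow(x)
    if (n <= t_out) return(x)
    grp <- cut(seq_len(n), t_out, labels = FALSE)
    out <- rowsum(x, grp) / as.vector(table(grp))
    out
  }
}

#' Reference EEG spatial encoder
#'
#' Stands in for a pre-trained convolutional EEG encoder (a Conformer-style
#' stack without self-attention): a small fixed seeded convolution over the
#' channel axis of the (channels x 5 bands) PSD matrix, ELU, global mean over
#' channels, tiled to `t_out` time steps. Band powers are log-compressed
#' first so the encoder sees scale-stable inputs.
#'
#' @param t_out Output time steps per block (default 8).
#' @param width Output feature width (default 16).
#' @param seed Seed for the fixed weights (the encoder is frozen, like a
#'   pre-trained model).
#' @return Encoder function.
#' @export
ref_eeg_encoder <- function(t_out = 8L, width = 16L, seed = 20240601L) {
  W <- with_local_seed(seed, {
    list(k = lapply(1:3, function(i)
      matrix(stats::rnorm(5L * width, sd = sqrt(2 / (5 + width))), 5L, width)),
      b = numeric(width))
  })
  function(x) {
    if (inherits(x, "eeg_band_psd")) x <- x$psd
    x <- log1p(as.matrix(x))                     # channels x 5
    n_ch <- nrow(x)
    out <- matrix(W$b, n_ch, length(W$b), byrow = TRUE)
    for (i in 1:3) {                             # kernel 3 over channels, same pad
      off <- i - 2L
      src <- pmin(pmax(seq_len(n_ch) + off, 1L), n_ch)
      out <- out + x[src, , drop = FALSE] %*% W$k[[i]]
    }
    v <- colMeans(elu_fwd(out))
    matrix(v, t_out, length(v), byrow = TRUE)
  }
}

register_default_encoders <- function(t_video = 16L, t_audio = 16L,
                                      t_eeg = 8L) {
  register_spatial_encoder("video", ref_video_encoder(t_video), NULL,
                           override = TRUE)
  register_spatial_encoder("audio", ref_audio_encoder(t_audio), NULL,
                           override = TRUE)
  register_spatial_encoder("eeg", ref_eeg_encoder(t_eeg), NULL,
                           override = TRUE)
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_default_encoders()
}

## ---- dilated causal convolution (sequence primitive) ----------------------

#' Dilated causal convolution of a sequence
#'
#' Computes `F(t) = sum_{i=0}^{k-1} f(i) * x(t - d*i)` with zero padding for
#' `t - d*i < 1`, so the output has the same length as the input and depends
#' only on current and past samples.
#'
#' @param x Numeric input sequence.
#' @param f Filter taps (length `k`); `f[1]` multiplies the current sample.
#' @param d Dilation rate (integer >= 1).
#' @return Numeric vector, same length as `x`.
#' @export
dilated_conv <- function(x, f, d = 1L) {
  if (length(x) == 0L) stopf("empty input sequence")
  if (length(f) == 0L) stopf("empty filter")
  if (d < 1L) stopf("dilation must be >= 1")
  n <- length(x)
  out <- numeric(n)
  for (i in seq_along(f)) {
    s <- d * (i - 1L)
    if (s >= n) break
    out[(s + 1L):n] <- out[(s + 1L):n] + f[i] * x[1L:(n - s)]
  }
  out
}

## ---- residual TCN ----------------------------------------------------------

#' Residual TCN configuration
#'
#' @param kernel_size Filter length `k` (default 3).
#' @param dilation_rates Dilation per block (default `c(1, 2, 4, 8)`).
#' @param n_blocks Number of residual blocks; must equal
#'   `length(dilation_rates)`.
#' @param dropout_rate Dropout rate inside each block (default 0.5).
#' @param channels Output feature width `D` (default 128).
#' @param convs_per_block One (default) or two dilated convolutions per block.
#' @param bn_momentum Running-statistics momentum for batch normalization.
#' @return Object of class `tcn_config`.
#' @export
tcn_config <- function(kernel_size = 3L, dilation_rates = c(1L, 2L, 4L, 8L),
                       n_blocks = length(dilation_rates), dropout_rate = 0.5,
                       channels = 128L, convs_per_block = 1L,
                       bn_momentum = 0.1) {
  if (kernel_size < 1L) stopf("`kernel_size` must be >= 1")
  if (n_blocks != length(dilation_rates))
    stopf("`dilation_rates` must have one entry per block")
  check_fraction(dropout_rate, "dropout_rate", hi_open = TRUE)
  if (!convs_per_block %in% 1:2) stopf("`convs_per_block` must be 1 or 2")
  structure(list(kernel_size = as.integer(kernel_size),
                 dilation_rates = as.integer(dilation_rates),
                 n_blocks = as.integer(n_blocks),
                 dropout_rate = dropout_rate,
                 channels = as.integer(channels),
                 convs_per_block = as.integer(convs_per_block),
                 bn_momentum = bn_momentum),
            class = "tcn_config")
}

#' Receptive field of a residual TCN
#'
#' `1 + convs_per_block * (kernel_size - 1) * sum(dilation_rates)` time steps.
#'
#' @param cfg A [tcn_config()].
#' @return Integer receptive field.
#' @export
tcn_receptive_field <- function(cfg) {
  1L + cfg$convs_per_block * (cfg$kernel_size - 1L) * sum(cfg$dilation_rates)
}

#' Initialize residual TCN parameters
#'
#' Draws weights from the current RNG stream; seed externally for
#' reproducibility.
#'
#' @param d_in Input feature width.
#' @param cfg A [tcn_config()].
#' @return Nested parameter list (one entry per block: dilated conv(s), batch
#'   norm scale/shift, and a 1x1 linear shortcut where widths differ).
#' @export
tcn_init <- function(d_in, cfg) {
  blocks <- vector("list", cfg$n_blocks)
  for (j in seq_len(cfg$n_blocks)) {
    dj <- if (j == 1L) d_in else cfg$channels
    bl <- list(conv1 = dconv_init(cfg$kernel_size, dj, cfg$channels),
               bn1 = bn_init(cfg$channels))
    if (cfg$convs_per_block == 2L) {
      bl$conv2 <- dconv_init(cfg$kernel_size, cfg$channels, cfg$channels)
      bl$bn2 <- bn_init(cfg$channels)
    }
    bl["shortcut"] <- if (dj != cfg$channels)
      list(list(W = nn_linear_init(dj, cfg$channels, bias = FALSE)$W))
    else list(NULL)
    blocks[[j]] <- bl
  }
  list(blocks = blocks)
}

tcn_state_init <- function(cfg) {
  list(blocks = lapply(seq_len(cfg$n_blocks), function(j) {
    st <- list(bn1 = bn_state_init(cfg$channels))
    if (cfg$convs_per_block == 2L) st$bn2 <- bn_state_init(cfg$channels)
    st
  }))
}

## Internal batched forward. X: (B*T) x D_in, time fastest within sample.
tcn_fwd <- function(X, B, T, params, state, cfg, train = FALSE) {
  caches <- vector("list", cfg$n_blocks)
  for (j in seq_len(cfg$n_blocks)) {
    bl <- params$blocks[[j]]
    d <- cfg$dilation_rates[j]
    cache <- list(inX = X)
    cv <- dconv_fwd(X, B, T, bl$conv1, d)
    bn <- bn_fwd(cv$out, bl$bn1, state$blocks[[j]]$bn1, train,
                 cfg$bn_momentum)
    state$blocks[[j]]$bn1 <- bn$state
    act <- elu_fwd(bn$out)
    dp <- dropout_fwd(act, cfg$dropout_rate, train)
    cache$conv1 <- cv; cache$bn1 <- bn$cache; cache$act1 <- act
    cache$dp1 <- dp$mask
    h <- dp$out
    if (cfg$convs_per_block == 2L) {
      cv2 <- dconv_fwd(h, B, T, bl$conv2, d)
      bn2 <- bn_fwd(cv2$out, bl$bn2, state$blocks[[j]]$bn2, train,
                    cfg$bn_momentum)
      state$blocks[[j]]$bn2 <- bn2$state
      act2 <- elu_fwd(bn2$out)
      dp2 <- dropout_fwd(act2, cfg$dropout_rate, train)
      cache$conv2 <- cv2; cache$bn2 <- bn2$cache; cache$act2 <- act2
      cache$dp2 <- dp2$mask
      h <- dp2$out
    }
    res <- if (!is.null(bl$shortcut)) cache$inX %*% bl$shortcut$W else cache$inX
    X <- h + res
    caches[[j]] <- cache
  }
  list(out = X, caches = caches, state = state)
}

tcn_bwd <- function(G, caches, params, cfg, B, T) {
  grads <- list(blocks = vector("list", cfg$n_blocks))
  for (j in rev(seq_len(cfg$n_blocks))) {
    bl <- params$blocks[[j]]
    cache <- caches[[j]]
    d <- cfg$dilation_rates[j]
    gbl <- list()
    Gh <- G
    if (cfg$convs_per_block == 2L) {
      Gh <- dropout_bwd(Gh, cache$dp2)
      Gh <- elu_bwd(Gh, cache$act2)
      b2 <- bn_bwd(Gh, cache$bn2, bl$bn2)
      gbl$bn2 <- b2$grads
      c2 <- dconv_bwd(b2$dX, cache$conv2, bl$conv2, d, B, T)
      gbl$conv2 <- c2$grads
      Gh <- c2$dX
    }
    Gh <- dropout_bwd(Gh, cache$dp1)
    Gh <- elu_bwd(Gh, cache$act1)
    b1 <- bn_bwd(Gh, cache$bn1, bl$bn1)
    gbl$bn1 <- b1$grads
    c1 <- dconv_bwd(b1$dX, cache$conv1, bl$conv1, d, B, T)
    gbl$conv1 <- c1$grads
    dIn <- c1$dX
    if (!is.null(bl$shortcut)) {
      gbl$shortcut <- list(W = crossprod(cache$inX, G))
      dIn <- dIn + G %*% t(bl$shortcut$W)
    } else {
      dIn <- dIn + G
    }
    ## grad tree must mirror the parameter tree (same names, same order)
    ordered <- lapply(names(bl), function(nm) gbl[[nm]])
    names(ordered) <- names(bl)
    grads$blocks[[j]] <- ordered
    G <- dIn
  }
  list(dX = G, grads = grads)
}

## Convert a (B, T, D) array to the internal (B*T) x D layout and back.
seq_to_mat <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(2L, 1L, 3L)), d[1] * d[2], d[3])
}
mat_to_seq <- function(X, B, T) {
  aperm(array(X, c(T, B, ncol(X))), c(2L, 1L, 3L))
}

#' Apply a residual TCN to spatial features
#'
#' Each block applies a dilated causal convolution, batch normalization, ELU,
#' dropout and a residual connection (with a 1x1 linear shortcut where the
#' input width differs from `channels`). With `train_mode = FALSE` the output
#' is deterministic: dropout is disabled and normalization uses running
#' statistics.
#'
#' @param s_m Spatial features: `T x D_in` matrix (one sample) or
#'   `B x T x D_in` array.
#' @param params Parameters from [tcn_init()]; created from the current RNG
#'   stream when `NULL`.
#' @param cfg A [tcn_config()].
#' @param train_mode Enable dropout and batch statistics.
#' @param state Batch-norm running statistics (fresh when `NULL`).
#' @return Spatiotemporal representation with the input's layout and feature
#'   width `cfg$channels`.
#' @export
residual_tcn <- function(s_m, params = NULL, cfg = tcn_config(),
                         train_mode = FALSE, state = NULL) {
  single <- is.matrix(s_m)
  a <- if (single) array(s_m, c(1L, nrow(s_m), ncol(s_m))) else s_m
  check_finite(a, "s_m")
  B <- dim(a)[1]; T <- dim(a)[2]; Din <- dim(a)[3]
  if (is.null(params)) params <- tcn_init(Din, cfg)
  if (is.null(state)) state <- tcn_state_init(cfg)
  fw <- tcn_fwd(seq_to_mat(a), B, T, params, state, cfg, train = train_mode)
  out <- mat_to_seq(fw$out, B, T)
  if (single) out[1, , ] else out
}
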