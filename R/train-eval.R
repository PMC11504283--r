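# Two-stage training (contrastive pre-training of the encoders, then
# fine-tuning of the cross-modal attention and classifier with frozen
# encoders), plus stratified fourfold cross-validation.

#' Training configuration
#'
#' @param pretrain_epochs,finetune_epochs Epochs per stage (both >= 1).
#' @param batch_size Mini-batch size (default 32).
#' @param lr_pretrain,lr_finetune Adam learning rates (defaults 1e-3 / 1e-4).
#' @param seed Seed fixing all stochastic components (initialization,
#'   shuffling, dropout).
#' @param freeze_encoders Keep encoder parameters fixed during fine-tuning
#'   (default TRUE; set FALSE to optimize them end-to-end as well).
#' @param weights A [mercl_weights()].
#' @param tcn A [tcn_config()].
#' @param proj_dim Shared projection width P (default 64).
#' @param normalize_embeddings L2-normalize projected embeddings
#'   (default TRUE).
#' @param n_heads Attention heads per cross-modal block (default 4).
#' @param classifier_hidden,classifier_dropout MLP head width and dropout.
#' @param fusion_pooling Pooling of each attention result over query time.
#' @param verbose Print per-epoch losses.
#' @param log_file Optional path; per-epoch loss terms and skip counts are
#'   appended as JSON lines for training diagnostics.
#' @return Object of class `train_config`.
#' @export
train_config <- function(pretrain_epochs = 10L, finetune_epochs = 30L,
                         batch_size = 32L, lr_pretrain = 1e-3,
                         lr_finetune = 1e-4, seed = 1L,
                         freeze_encoders = TRUE,
                         weights = mercl_weights(), tcn = tcn_config(),
                         proj_dim = 64L, normalize_embeddings = TRUE,
                         n_heads = 4L, classifier_hidden = 256L,
                         classifier_dropout = 0.1,
                         fusion_pooling = c("mean", "last"),
                         verbose = FALSE, log_file = NULL) {
  if (pretrain_epochs < 1L || finetune_epochs < 1L)
    stopf("epoch counts must be >= 1")
  stopifnot(inherits(weights, "mercl_weights"), inherits(tcn, "tcn_config"))
  structure(list(pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 batch_size = as.integer(batch_size),
                 lr_pretrain = lr_pretrain, lr_finetune = lr_finetune,
                 seed = as.integer(seed),
                 freeze_encoders = isTRUE(freeze_encoders),
                 weights = weights, tcn = tcn,
                 proj_dim = as.integer(proj_dim),
                 normalize_embeddings = isTRUE(normalize_embeddings),
                 n_heads = as.integer(n_heads),
                 classifier_hidden = as.integer(classifier_hidden),
                 classifier_dropout = classifier_dropout,
                 fusion_pooling = match.arg(fusion_pooling),
                 verbose = isTRUE(verbose), log_file = log_file),
            class = "train_config")
}

#' Preprocess a dataset into aligned per-block features
#'
#' Segments every trial into blocks, computes the per-modality features
#' (video spatial features, audio log-Mel spectrogram, EEG band PSD), applies
#' the registered spatial encoders and flags low/absent-energy audio blocks
#' over the whole batch.
#'
#' @param dataset A `synth_dataset`, or a list of [trial_record()]s.
#' @param block_len_s,overlap_frac,lag_s Passed to [segment_trial()].
#' @param band_edges EEG bands for [eeg_band_psd()].
#' @param n_mels,window_ms,hop_ms Audio analysis parameters for
#'   [log_mel_spectrogram()].
#' @param energy_threshold_mode,energy_threshold_value Passed to
#'   [audio_energy_select()].
#' @return Object of class `mercl_features`: `s` (named list of `B x T x D_m`
#'   spatial feature arrays), `labels`, `trial` (block-to-trial map),
#'   `energy` (flags tibble) and the preprocessing parameters.
#' @export
prepare_blocks <- function(dataset, block_len_s = 4, overlap_frac = 0.5,
                           lag_s = c(video = 0, audio = 0, eeg = 0),
                           band_edges = default_band_edges(),
                           n_mels = 20L, window_ms = 50, hop_ms = 10,
                           energy_threshold_mode = "percentile",
                           energy_threshold_value = 5) {
  trials <- if (inherits(dataset, "synth_dataset")) dataset$trials else dataset
  stopifnot(length(trials) > 0L,
            all(vapply(trials, inherits, logical(1), "trial_record")))
  sv <- list(); sa <- list(); se <- list()
  labels <- integer(0); trial_ids <- character(0); audio_blocks <- list()
  for (tr in trials) {
    bs <- segment_trial(tr, block_len_s, overlap_frac, lag_s)
    for (blk in bs$blocks) {
      sv[[length(sv) + 1L]] <- encode_spatial("video", blk$video)
      lms <- log_mel_spectrogram(blk$audio, tr$audio_fs, window_ms, hop_ms,
                                 n_mels)
      sa[[length(sa) + 1L]] <- encode_spatial("audio", lms)
      psd <- eeg_band_psd(blk$eeg, tr$eeg_fs, band_edges)
      se[[length(se) + 1L]] <- encode_spatial("eeg", psd)
      audio_blocks[[length(audio_blocks) + 1L]] <- blk$audio
      labels <- c(labels, tr$label)
      trial_ids <- c(trial_ids, tr$trial_id)
    }
  }
  stack <- function(lst) {
    T <- nrow(lst[[1]]); D <- ncol(lst[[1]])
    a <- array(0, c(length(lst), T, D))
    for (i in seq_along(lst)) a[i, , ] <- lst[[i]]
    a
  }
  energy <- audio_energy_select(audio_blocks, energy_threshold_mode,
                                energy_threshold_value)
  structure(list(s = list(video = stack(sv), audio = stack(sa),
                          eeg = stack(se)),
                 labels = as.integer(labels), trial = trial_ids,
                 energy = energy,
                 params = list(block_len_s = block_len_s,
                               overlap_frac = overlap_frac, lag_s = lag_s,
                               n_mels = n_mels, window_ms = window_ms,
                               hop_ms = hop_ms)),
            class = "mercl_features")
}

#' @export
print.mercl_features <- function(x, ...) {
  d <- vapply(x$s, function(a) sprintf("%dx%d", dim(a)[2], dim(a)[3]),
              character(1))
  cat(sprintf("<mercl_features> %d blocks from %d trials | video %s, audio %s, eeg %s | %d audio-absent\n",
              length(x$labels), length(unique(x$trial)),
              d["video"], d["audio"], d["eeg"], sum(!x$energy$is_present)))
  invisible(x)
}

## Subset a feature object by block indices.
features_subset <- function(features, idx) {
  out <- features
  out$s <- lapply(features$s, function(a) a[idx, , , drop = FALSE])
  out$labels <- features$labels[idx]
  out$trial <- features$trial[idx]
  out$energy <- features$energy[idx, , drop = FALSE]
  out
}

## Append one JSON line of training diagnostics when cfg$log_file is set.
log_jsonl <- function(cfg, record) {
  if (is.null(cfg$log_file)) return(invisible(NULL))
  cat(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = cfg$log_file, append = TRUE)
}

#' Initialize an untrained encoder stack
#'
#' Residual-TCN parameters for each modality plus the shared-space projection
#' matrices, drawn under `cfg$seed`. [pretrain()] starts from exactly this
#' state, so it also serves as the random-initialization baseline for
#' embedding-quality comparisons.
#'
#' @param features A `mercl_features`.
#' @param cfg A [train_config()].
#' @return Object of class `mercl_encoder` (untrained).
#' @export
init_encoder <- function(features, cfg = train_config()) {
  stopifnot(inherits(features, "mercl_features"))
  with_local_seed(cfg$seed, {
    d_in <- lapply(features$s, function(a) dim(a)[3])
    params <- list(
      tcn = lapply(d_in, function(d) tcn_init(d, cfg$tcn)),
      proj = lapply(d_in, function(d)
        nn_linear_init(cfg$tcn$channels, cfg$proj_dim, bias = FALSE)$W))
    structure(list(params = params,
                   bn_state = lapply(d_in, function(d) tcn_state_init(cfg$tcn)),
                   d_in = d_in, cfg = cfg, trained = FALSE,
                   loss_log = NULL),
              class = "mercl_encoder")
  })
}

#' @export
print.mercl_encoder <- function(x, ...) {
  cat(sprintf("<mercl_encoder> D=%d, P=%d, %s\n", x$cfg$tcn$channels,
              x$cfg$proj_dim,
              if (isTRUE(x$trained)) sprintf("pre-trained %d epochs",
                                             max(x$loss_log$epoch))
              else "untrained"))
  invisible(x)
}

## Forward one modality through TCN + pooling (+ projection), with caches.
encoder_fwd_modality <- function(a, tcn_params, bn_state, cfg, train) {
  B <- dim(a)[1]; T <- dim(a)[2]
  X <- seq_to_mat(a)
  fw <- tcn_fwd(X, B, T, tcn_params, bn_state, cfg$tcn, train = train)
  pooled <- rowsum(fw$out, rep(seq_len(B), each = T)) / T
  list(fw = fw, pooled = pooled, B = B, T = T)
}

## Projection + optional normalization with cache for backward.
project_fwd <- function(pooled, W, normalize) {
  z0 <- pooled %*% W
  if (!normalize) return(list(z = z0, z0 = z0, nrm = NULL))
  nrm <- sqrt(rowSums(z0^2))
  nrm[nrm == 0] <- 1
  list(z = z0 / nrm, z0 = z0, nrm = nrm)
}

project_bwd <- function(dz, cache, pooled, W, normalize) {
  if (normalize) {
    z <- cache$z
    dz0 <- (dz - z * rowSums(z * dz)) / cache$nrm
  } else dz0 <- dz
  list(dW = crossprod(pooled, dz0), dpooled = dz0 %*% t(W))
}

#' Stage 1: contrastive pre-training of the encoders
#'
#' Runs mini-batch Adam on the combined contrastive loss over the projected
#' embeddings of all three modalities (Stage 1 of the two-stage procedure).
#' Deterministic given `cfg$seed` and a fixed thread count.
#'
#' @param features A `mercl_features` (aligned three-modality block features
#'   with labels).
#' @param cfg A [train_config()].
#' @return A trained `mercl_encoder` with a per-epoch loss log
#'   (`loss_log`: total and unweighted per-term means, skip counts).
#' @export
pretrain <- function(features, cfg = train_config()) {
  enc <- init_encoder(features, cfg)
  params <- enc$params
  bn_state <- enc$bn_state
  mods <- names(features$s)
  B_all <- length(features$labels)
  flags <- features$energy$is_present
  norm <- cfg$normalize_embeddings
  opt <- adam_init(params)
  log_rows <- list()
  with_local_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$pretrain_epochs)) {
      ord <- sample.int(B_all)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep <- c(total = 0, amcl = 0, emcl = 0, smcl = 0)
      ep_skip <- c(amcl = 0L, emcl = 0L, smcl = 0L)
      for (idx in batches) {
        fwd <- list(); pr <- list(); z_all <- list()
        for (m in mods) {
          f <- encoder_fwd_modality(features$s[[m]][idx, , , drop = FALSE],
                                    params$tcn[[m]], bn_state[[m]], cfg, TRUE)
          bn_state[[m]] <- f$fw$state
          p <- project_fwd(f$pooled, params$proj[[m]], norm)
          fwd[[m]] <- f; pr[[m]] <- p; z_all[[m]] <- p$z
        }
        lg <- mercl_loss_grad(z_all, features$labels[idx], cfg$weights,
                              flags[idx])
        if (!is.finite(lg$total)) {
          bad <- names(lg$terms)[!is.finite(lg$terms)]
          stopf("pre-training diverged (non-finite %s term) at epoch %d",
                paste(bad, collapse = "/"), epoch)
        }
        grads <- list(tcn = list(), proj = list())
        for (m in mods) {
          pb <- project_bwd(lg$grads[[m]], pr[[m]], fwd[[m]]$pooled,
                            params$proj[[m]], norm)
          grads$proj[[m]] <- pb$dW
          Tm <- fwd[[m]]$T
          G <- pb$dpooled[rep(seq_along(idx), each = Tm), , drop = FALSE] / Tm
          tb <- tcn_bwd(G, fwd[[m]]$fw$caches, params$tcn[[m]], cfg$tcn,
                        fwd[[m]]$B, Tm)
          grads$tcn[[m]] <- tb$grads
        }
        st <- adam_step(params, grads, opt, cfg$lr_pretrain)
        params <- st$params; opt <- st$state
        w <- length(idx) / B_all
        ep <- ep + w * c(lg$total, ifelse(is.na(lg$terms), 0, lg$terms))
        ep_skip <- ep_skip + lg$skipped
      }
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch, total = ep[["total"]], amcl = ep[["amcl"]],
        emcl = ep[["emcl"]], smcl = ep[["smcl"]],
        skipped_amcl = ep_skip[["amcl"]], skipped_emcl = ep_skip[["emcl"]],
        skipped_smcl = ep_skip[["smcl"]])
      log_jsonl(cfg, c(list(stage = "pretrain"),
                       as.list(log_rows[[epoch]])))
      if (cfg$verbose)
        message(sprintf("pretrain epoch %d: loss %.4f", epoch, ep[["total"]]))
    }
  })
  enc$params <- params
  enc$bn_state <- bn_state
  enc$trained <- TRUE
  enc$loss_log <- do.call(rbind, log_rows)
  enc
}

#' Encode features into spatiotemporal representations
#'
#' Runs the (trained) residual TCNs in evaluation mode: dropout off, batch
#' normalization on running statistics, so the output is deterministic.
#'
#' @param encoder A `mercl_encoder`.
#' @param features A `mercl_features`.
#' @return Named list of `B x T_m x D` arrays.
#' @export
encode_features <- function(encoder, features) {
  mods <- names(features$s)
  out <- lapply(mods, function(m) {
    f <- encoder_fwd_modality(features$s[[m]], encoder$params$tcn[[m]],
                              encoder$bn_state[[m]], encoder$cfg, FALSE)
    mat_to_seq(f$fw$out, f$B, f$T)
  })
  names(out) <- mods
  out
}

#' Project features into the shared embedding space
#'
#' @param encoder A `mercl_encoder`.
#' @param features A `mercl_features`.
#' @return Named list of `B x P` embedding matrices.
#' @export
embed_features <- function(encoder, features) {
  h <- encode_features(encoder, features)
  out <- lapply(names(h), function(m)
    project(h[[m]], encoder$params$proj[[m]],
            normalize = encoder$cfg$normalize_embeddings))
  names(out) <- names(h)
  out
}

#' Silhouette score of class clusters in the shared space
#'
#' Pools the three modalities' embeddings into one point cloud (the shared
#' space contains all of them) and computes the mean silhouette width of the
#' class clustering.
#'
#' @param z_all Named list of `B x P` embedding matrices.
#' @param labels Integer labels, length `B`.
#' @return Mean silhouette width.
#' @export
silhouette_score <- function(z_all, labels) {
  pts <- do.call(rbind, z_all)
  lab <- rep(labels, length(z_all))
  sil <- cluster::silhouette(as.integer(factor(lab)), stats::dist(pts))
  mean(sil[, "sil_width"])
}

#' Stage 2: fine-tune cross-modal attention and classifier
#'
#' Encodes the dataset with the pre-trained encoders (frozen by default, per
#' the two-stage procedure), then trains the six directed attention blocks
#' and the MLP head with Adam on the cross-entropy. With
#' `cfg$freeze_encoders = FALSE` the encoder parameters are optimized jointly
#' as well.
#'
#' @param features A `mercl_features`.
#' @param encoder A (pre-trained) `mercl_encoder`.
#' @param cfg A [train_config()].
#' @return Object of class `mercl_model` (encoder, attention and classifier
#'   parameters, class levels, loss log).
#' @export
finetune <- function(features, encoder, cfg = train_config()) {
  stopifnot(inherits(encoder, "mercl_encoder"))
  mods <- names(features$s)
  B_all <- length(features$labels)
  classes <- sort(unique(features$labels))
  y <- match(features$labels, classes)
  D <- cfg$tcn$channels
  freeze <- cfg$freeze_encoders
  enc_params <- encoder$params
  bn_state <- encoder$bn_state

  h_full <- if (freeze) encode_features(encoder, features) else NULL

  with_local_seed(cfg$seed + 2L, {
    params <- list(cma = cma_init(D, cfg$n_heads),
                   clf = classifier_init(6L * D, length(classes),
                                         cfg$classifier_hidden))
    if (!freeze) params$tcn <- enc_params$tcn
    opt <- adam_init(params)
    log_rows <- list()
    for (epoch in seq_len(cfg$finetune_epochs)) {
      ord <- sample.int(B_all)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0; ep_acc <- 0
      for (idx in batches) {
        if (freeze) {
          h <- lapply(h_full, function(a) a[idx, , , drop = FALSE])
          enc_fw <- NULL
        } else {
          enc_fw <- list(); h <- list()
          for (m in mods) {
            f <- encoder_fwd_modality(features$s[[m]][idx, , , drop = FALSE],
                                      params$tcn[[m]], bn_state[[m]], cfg,
                                      TRUE)
            bn_state[[m]] <- f$fw$state
            enc_fw[[m]] <- f
            h[[m]] <- mat_to_seq(f$fw$out, f$B, f$T)
          }
        }
        fw <- cma_fwd_batch(h, params$cma, cfg$fusion_pooling)
        mf <- mlp_fwd(fw$concat, params$clf, cfg$classifier_dropout,
                      train = TRUE)
        ce <- ce_fwd_bwd(mf$logits, y[idx])
        if (!is.finite(ce$loss))
          stopf("fine-tuning diverged (non-finite cross-entropy) at epoch %d",
                epoch)
        mb <- mlp_bwd(ce$grad, mf$cache, params$clf)
        cb <- cma_bwd_batch(mb$dX, fw, h, params$cma,
                            need_input_grads = !freeze)
        grads <- list(cma = cb$grads, clf = mb$grads)
        if (!freeze) {
          grads$tcn <- list()
          for (m in mods) {
            G <- seq_to_mat(cb$dh[[m]])
            tb <- tcn_bwd(G, enc_fw[[m]]$fw$caches, params$tcn[[m]],
                          cfg$tcn, enc_fw[[m]]$B, enc_fw[[m]]$T)
            grads$tcn[[m]] <- tb$grads
          }
        }
        st <- adam_step(params, grads, opt, cfg$lr_finetune)
        params <- st$params; opt <- st$state
        w <- length(idx) / B_all
        ep_loss <- ep_loss + w * ce$loss
        ep_acc <- ep_acc + w * mean(max.col(ce$probs) == y[idx])
      }
      log_rows[[epoch]] <- tibble::tibble(epoch = epoch,
                                          cross_entropy = ep_loss,
                                          train_accuracy = ep_acc)
      log_jsonl(cfg, c(list(stage = "finetune"),
                       as.list(log_rows[[epoch]])))
      if (cfg$verbose)
        message(sprintf("finetune epoch %d: ce %.4f acc %.3f",
                        epoch, ep_loss, ep_acc))
    }
    if (!freeze) {
      encoder$params$tcn <- params$tcn
      encoder$bn_state <- bn_state
    }
    structure(list(encoder = encoder, cma = params$cma, clf = params$clf,
                   classes = classes, cfg = cfg,
                   loss_log = do.call(rbind, log_rows)),
              class = "mercl_model")
  })
}

#' @export
print.mercl_model <- function(x, ...) {
  ll <- x$loss_log
  cat(sprintf("<mercl_model> %d classes | final train CE %.4f, accuracy %.3f\n",
              length(x$classes), ll$cross_entropy[nrow(ll)],
              ll$train_accuracy[nrow(ll)]))
  invisible(x)
}

#' Predict emotion classes for preprocessed blocks
#'
#' @param object A `mercl_model`.
#' @param features A `mercl_features`.
#' @param ... Unused.
#' @return A tibble with the predicted class (`pred`, in the training label
#'   coding) and one probability column per class.
#' @export
predict.mercl_model <- function(object, features, ...) {
  h <- encode_features(object$encoder, features)
  fused <- cma_fwd_batch(h, object$cma, object$cfg$fusion_pooling)
  pred <- classify(fused$concat, object$clf)
  out <- tibble::tibble(pred = object$classes[pred$label_idx])
  probs <- as.data.frame(pred$probs)
  names(probs) <- paste0("p_", object$classes)
  cbind(out, tibble::as_tibble(probs))
}

#' Accuracy and F1 from binary confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)` and
#' `F1 = 2 TP / (2 TP + FP + FN)`.
#'
#' @param tp,tn,fp,fn Nonnegative confusion counts.
#' @return List with `accuracy` and `f1`.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stopf("confusion counts must be nonnegative")
  total <- tp + tn + fp + fn
  if (total == 0) stopf("no decisions to evaluate")
  list(accuracy = (tp + tn) / total,
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
}

#' Classification metrics from predictions
#'
#' Overall accuracy plus per-class one-vs-rest confusion counts and F1; the
#' multiclass F1 is the macro average over classes, with the convention that
#' a class with `TP = FP = FN = 0` contributes F1 = 0 (such classes are
#' flagged in the per-class table).
#'
#' @param predictions Predicted labels.
#' @param labels True labels (same length and coding).
#' @return Object of class `mercl_metrics`: `accuracy`, `f1_macro`,
#'   `per_class` tibble and `n`.
#' @export
compute_metrics <- function(predictions, labels) {
  if (length(predictions) == 0L || length(labels) == 0L)
    stopf("empty predictions or labels")
  if (length(predictions) != length(labels))
    stopf("predictions and labels differ in length")
  classes <- sort(unique(c(predictions, labels)))
  per <- lapply(classes, function(cl) {
    tp <- sum(predictions == cl & labels == cl)
    fp <- sum(predictions == cl & labels != cl)
    fn <- sum(predictions != cl & labels == cl)
    tn <- sum(predictions != cl & labels != cl)
    degenerate <- (tp + fp + fn) == 0
    tibble::tibble(class = cl, tp = tp, tn = tn, fp = fp, fn = fn,
                   f1 = if (degenerate) 0 else 2 * tp / (2 * tp + fp + fn),
                   degenerate = degenerate)
  })
  per <- do.call(rbind, per)
  structure(list(accuracy = mean(predictions == labels),
                 f1_macro = mean(per$f1), per_class = per,
                 n = length(labels)),
            class = "mercl_metrics")
}

#' @export
print.mercl_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro F1 %.4f (n = %d)\n",
              x$accuracy, x$f1_macro, x$n))
  invisible(x)
}

## Seeded stratified fold assignment. The remainder folds rotate across
## classes so overall fold sizes stay balanced even when class counts are
## not multiples of k.
stratified_folds <- function(labels, k, seed) {
  with_local_seed(seed, {
    f <- integer(length(labels))
    offset <- 0L
    for (cl in sort(unique(labels))) {
      i <- which(labels == cl)
      lab <- (seq_along(i) - 1L + offset) %% k + 1L
      f[i] <- sample(lab)
      offset <- (offset + length(i)) %% k
    }
    f
  })
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Assigns whole trials to folds (stratified by class, so overlapping blocks
#' from one trial never straddle the train/test split), then runs
#' pre-training, fine-tuning and evaluation per fold.
#'
#' @param dataset A `synth_dataset` or list of [trial_record()]s.
#' @param cfg A [train_config()].
#' @param k Number of folds (default 4).
#' @param features Optional precomputed [prepare_blocks()] output (the
#'   preprocessing is label-independent and per-trial, so it is shared across
#'   folds).
#' @param ... Further arguments to [prepare_blocks()].
#' @return Object of class `mercl_cv`: per-fold metrics, mean and sd across
#'   folds, the trial-to-fold map and the configuration snapshot.
#' @export
cross_validate <- function(dataset, cfg = train_config(), k = 4L,
                           features = NULL, ...) {
  if (is.null(features)) features <- prepare_blocks(dataset, ...)
  trial_ids <- unique(features$trial)
  trial_label <- features$labels[match(trial_ids, features$trial)]
  counts <- table(trial_label)
  if (any(counts < k))
    stopf(paste("class %s has %d trial(s); stratified %d-fold CV needs at",
                "least %d per class. Reduce k or add trials."),
          names(counts)[which.min(counts)], min(counts), k, k)
  fold_of <- stratified_folds(trial_label, k, cfg$seed)
  folds <- list()
  for (fold in seq_len(k)) {
    test_trials <- trial_ids[fold_of == fold]
    te <- features$trial %in% test_trials
    enc <- pretrain(features_subset(features, which(!te)), cfg)
    model <- finetune(features_subset(features, which(!te)), enc, cfg)
    test_feats <- features_subset(features, which(te))
    pred <- predict(model, test_feats)
    met <- compute_metrics(pred$pred, test_feats$labels)
    folds[[fold]] <- tibble::tibble(fold = fold, accuracy = met$accuracy,
                                    f1_macro = met$f1_macro,
                                    n_test = met$n)
    if (cfg$verbose)
      message(sprintf("fold %d: accuracy %.3f", fold, met$accuracy))
  }
  folds <- do.call(rbind, folds)
  structure(list(folds = folds,
                 mean_accuracy = mean(folds$accuracy),
                 sd_accuracy = stats::sd(folds$accuracy),
                 mean_f1 = mean(folds$f1_macro),
                 sd_f1 = stats::sd(folds$f1_macro),
                 fold_map = tibble::tibble(trial = trial_ids,
                                           label = trial_label,
                                           fold = fold_of),
                 cfg = cfg, k = k),
            class = "mercl_cv")
}

#' @export
print.mercl_cv <- function(x, ...) {
  cat(sprintf("<mercl_cv> %d-fold | accuracy %.4f +/- %.4f | macro F1 %.4f +/- %.4f\n",
              x$k, x$mean_accuracy, x$sd_accuracy, x$mean_f1, x$sd_f1))
  print(x$folds)
  invisible(x)
}
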