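# The combined contrastive objective: an intra-modal term (AMCL), an
# inter-modal term (EMCL) and a sample-wise alignment term (SMCL), each
# built from supervised positive/negative sets over a shared projected
# embedding space, with audio-energy-based exclusion of silent samples.

MODALITIES <- c("video", "audio", "eeg")

#' Weights and hyperparameters of the combined contrastive loss
#'
#' @param lambda1,lambda2,lambda3 Nonnegative weights of the intra-modal,
#'   inter-modal and sample-wise terms (all default 1); not all zero.
#' @param alpha Modality margin of the sample-wise term: the target
#'   cross-modal similarity within a sample (default 0.8; must lie in (0, 1]
#'   for normalized embeddings).
#' @param temperature Softening temperature applied as `exp(s / temperature)`
#'   to each similarity in the ratio terms (default 0.1).
#' @param literal_mode Use raw inner products instead of the softened
#'   exponential form. The literal ratio's logarithm is undefined when the
#'   summed similarities are nonpositive; literal mode raises an error in
#'   that case rather than returning NaN.
#' @return Object of class `mercl_weights`.
#' @export
mercl_weights <- function(lambda1 = 1, lambda2 = 1, lambda3 = 1,
                          alpha = 0.8, temperature = 0.1,
                          literal_mode = FALSE) {
  l <- c(lambda1, lambda2, lambda3)
  if (any(l < 0) || all(l == 0))
    stopf("loss weights must be nonnegative and not all zero")
  if (alpha <= 0 || alpha > 1)
    stopf("`alpha` must be in (0, 1] for normalized embeddings")
  if (temperature <= 0) stopf("`temperature` must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 alpha = alpha, temperature = temperature,
                 literal_mode = isTRUE(literal_mode)),
            class = "mercl_weights")
}

#' Project spatiotemporal representations into the shared embedding space
#'
#' Pools each sample's representation over time, applies the modality's
#' projection matrix (`z = pooled %*% W_m`, a bias-free linear map) and
#' optionally L2-normalizes each embedding row.
#'
#' @param h_m `T x D` matrix (one sample) or `B x T x D` array.
#' @param W_m `D x P` projection matrix.
#' @param pooling Temporal pooling: `"mean"` (default), `"last"` or `"max"`.
#' @param normalize L2-normalize embedding rows (default TRUE).
#' @return `B x P` matrix of embeddings (one row per sample).
#' @export
project <- function(h_m, W_m, pooling = c("mean", "last", "max"),
                    normalize = TRUE) {
  pooling <- match.arg(pooling)
  if (is.matrix(h_m)) h_m <- array(h_m, c(1L, nrow(h_m), ncol(h_m)))
  pooled <- pool_time(h_m, pooling)
  if (ncol(pooled) != nrow(W_m))
    stopf("projection expects width %d, got representations of width %d",
          nrow(W_m), ncol(pooled))
  z <- pooled %*% W_m
  if (normalize) z <- l2_normalize_rows(z)
  z
}

## Pool a (B, T, D) array over time.
pool_time <- function(a, pooling = "mean") {
  B <- dim(a)[1]; T <- dim(a)[2]; D <- dim(a)[3]
  switch(pooling,
         mean = {
           X <- matrix(aperm(a, c(2L, 1L, 3L)), B * T, D)
           unname(rowsum(X, rep(seq_len(B), each = T))) / T
         },
         last = matrix(a[, T, , drop = FALSE], B, D),
         max = apply(a, c(1L, 3L), max))
}

## is_present flags as a logical vector of length B (NULL -> all present).
as_present <- function(energy_flags, B) {
  if (is.null(energy_flags)) return(rep(TRUE, B))
  if (is.data.frame(energy_flags)) energy_flags <- energy_flags$is_present
  flags <- as.logical(energy_flags)
  if (length(flags) != B)
    stopf("energy flags length %d does not match batch size %d",
          length(flags), B)
  flags
}

#' Build the contrastive set for one anchor
#'
#' Supervised pair construction. For the intra-modal scheme (`"amcl"`)
#' positives are same-class, same-modality embeddings of *other* samples and
#' negatives are different-class embeddings of the same modality. For the
#' inter-modal scheme (`"emcl"`) positives/negatives are drawn from the two
#' non-anchor modalities (same-class other samples vs different-class
#' samples). For the sample-wise scheme (`"smcl"`) the positives are the
#' anchor sample's own embeddings in the other two modalities and there are
#' no negatives. In every scheme, audio embeddings whose energy flag marks
#' the audio absent are removed before set construction; an audio-modality
#' anchor that is itself flagged absent is skipped.
#'
#' @param z_all Named list of `B x P` embedding matrices
#'   (`video`, `audio`, `eeg`).
#' @param labels Integer class labels, length `B`.
#' @param anchor_idx Sample index of the anchor (1-based).
#' @param anchor_modality `"video"`, `"audio"` or `"eeg"`.
#' @param scheme `"amcl"`, `"emcl"` or `"smcl"`.
#' @param energy_flags Optional logical vector (or tibble from
#'   [audio_energy_select()]) of per-sample audio-present flags.
#' @return Object of class `contrastive_set` (anchor row, positives matrix,
#'   negatives matrix, source tags), or `NULL` as a skip-anchor signal when
#'   no positive is available.
#' @export
build_pairs <- function(z_all, labels, anchor_idx, anchor_modality,
                        scheme = c("amcl", "emcl", "smcl"),
                        energy_flags = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(anchor_modality %in% names(z_all))
  B <- nrow(z_all[[anchor_modality]])
  present <- as_present(energy_flags, B)
  valid <- function(m) if (m == "audio") present else rep(TRUE, B)

  if (!valid(anchor_modality)[anchor_idx]) return(NULL)
  anchor <- z_all[[anchor_modality]][anchor_idx, ]
  y0 <- labels[anchor_idx]
  others <- setdiff(names(z_all), anchor_modality)

  if (scheme == "amcl") {
    v <- valid(anchor_modality)
    pos <- which(v & labels == y0 & seq_len(B) != anchor_idx)
    neg <- which(v & labels != y0)
    if (length(pos) == 0L) return(NULL)
    positives <- z_all[[anchor_modality]][pos, , drop = FALSE]
    negatives <- z_all[[anchor_modality]][neg, , drop = FALSE]
    tags <- list(pos = rep(anchor_modality, length(pos)),
                 neg = rep(anchor_modality, length(neg)))
  } else if (scheme == "emcl") {
    positives <- NULL; negatives <- NULL
    ptags <- character(0); ntags <- character(0)
    for (m in others) {
      v <- valid(m)
      pos <- which(v & labels == y0 & seq_len(B) != anchor_idx)
      neg <- which(v & labels != y0)
      positives <- rbind(positives, z_all[[m]][pos, , drop = FALSE])
      negatives <- rbind(negatives, z_all[[m]][neg, , drop = FALSE])
      ptags <- c(ptags, rep(m, length(pos)))
      ntags <- c(ntags, rep(m, length(neg)))
    }
    if (is.null(positives) || nrow(positives) == 0L) return(NULL)
    if (is.null(negatives))
      negatives <- matrix(0, 0L, length(anchor))
    tags <- list(pos = ptags, neg = ntags)
  } else {
    keep <- others[vapply(others, function(m) valid(m)[anchor_idx],
                          logical(1))]
    if (length(keep) == 0L) return(NULL)
    positives <- do.call(rbind, lapply(keep, function(m)
      z_all[[m]][anchor_idx, , drop = FALSE]))
    negatives <- matrix(0, 0L, length(anchor))
    tags <- list(pos = keep, neg = character(0))
  }
  structure(list(anchor = anchor, positives = positives,
                 negatives = negatives, anchor_modality = anchor_modality,
                 anchor_idx = anchor_idx, scheme = scheme, tags = tags),
            class = "contrastive_set")
}

## Shared ratio loss of the intra- and inter-modal terms, for one anchor.
contrastive_ratio_loss <- function(sim_pos, sim_neg, weights) {
  if (length(sim_pos) == 0L) stopf("contrastive set has no positives")
  if (weights$literal_mode) {
    num <- sum(sim_pos)
    den <- num + sum(sim_neg)
    if (num <= 0 || den <= 0)
      stopf(paste("literal-mode ratio is nonpositive (numerator %.4g,",
                  "denominator %.4g); use the softened mode"), num, den)
    return(-log(num / den))
  }
  tau <- weights$temperature
  logsumexp(c(sim_pos, sim_neg) / tau) - logsumexp(sim_pos / tau)
}

#' Intra-modal contrastive loss for one anchor
#'
#' The negative log ratio of summed anchor-positive similarities to the sum
#' over positives and negatives, all within the anchor's modality. In the
#' default softened mode each similarity `s` enters as
#' `exp(s / temperature)`, which keeps the ratio structure while guaranteeing
#' a defined, nonnegative loss; `literal_mode` uses the raw inner products.
#'
#' @param set A `contrastive_set` from [build_pairs()].
#' @param weights A [mercl_weights()].
#' @return Scalar loss.
#' @export
amcl_loss <- function(set, weights = mercl_weights()) {
  stopifnot(inherits(set, "contrastive_set"))
  contrastive_ratio_loss(drop(set$positives %*% set$anchor),
                         drop(set$negatives %*% set$anchor), weights)
}

#' Inter-modal contrastive loss for one anchor
#'
#' Identical functional form to [amcl_loss()], with positives and negatives
#' drawn from the two non-anchor modalities (the set-size-agnostic ratio).
#'
#' @inheritParams amcl_loss
#' @return Scalar loss.
#' @export
emcl_loss <- function(set, weights = mercl_weights()) {
  stopifnot(inherits(set, "contrastive_set"))
  contrastive_ratio_loss(drop(set$positives %*% set$anchor),
                         drop(set$negatives %*% set$anchor), weights)
}

#' Sample-wise alignment loss for one anchor
#'
#' `0.5 * sum_i (s_i - alpha)^2` over the surviving cross-modal similarities
#' `s_i` between the anchor and its own sample's other-modality embeddings.
#' Zero exactly when every similarity equals the margin `alpha`.
#'
#' @param z_anchor Anchor embedding row.
#' @param positives Matrix of one or two other-modality embeddings of the
#'   same sample (rows), or a single vector.
#' @param alpha Modality margin.
#' @return Scalar loss.
#' @export
smcl_loss <- function(z_anchor, positives, alpha = 0.8) {
  if (is.null(dim(positives))) positives <- matrix(positives, nrow = 1L)
  if (nrow(positives) == 0L) stopf("no surviving positive for this anchor")
  s <- drop(positives %*% z_anchor)
  0.5 * sum((s - alpha)^2)
}

#' Combined multimodal contrastive loss over a batch
#'
#' Iterates anchors over every sample and every modality, builds the three
#' contrastive sets per anchor via [build_pairs()], and returns the
#' lambda-weighted total together with the three unweighted term means (the
#' expectation over anchors is the arithmetic mean over valid anchors) and
#' per-term skip counts. Terms with a zero lambda are still computed for
#' logging.
#'
#' @param z_all Named list of `B x P` embedding matrices.
#' @param labels Integer labels, length `B`.
#' @param weights A [mercl_weights()].
#' @param energy_flags Optional audio-present flags (see [build_pairs()]).
#' @return Object of class `mercl_loss`: `total`, `amcl`, `emcl`, `smcl`,
#'   `skipped` (per-term counts) and `n_anchors`.
#' @export
mercl_loss <- function(z_all, labels, weights = mercl_weights(),
                       energy_flags = NULL) {
  B <- nrow(z_all[[1]])
  mods <- names(z_all)
  vals <- list(amcl = numeric(0), emcl = numeric(0), smcl = numeric(0))
  skipped <- c(amcl = 0L, emcl = 0L, smcl = 0L)
  for (m in mods) {
    for (i in seq_len(B)) {
      for (sc in c("amcl", "emcl", "smcl")) {
        set <- build_pairs(z_all, labels, i, m, sc, energy_flags)
        if (is.null(set)) {
          skipped[sc] <- skipped[sc] + 1L
        } else if (sc == "smcl") {
          vals$smcl <- c(vals$smcl,
                         smcl_loss(set$anchor, set$positives, weights$alpha))
        } else {
          fn <- if (sc == "amcl") amcl_loss else emcl_loss
          vals[[sc]] <- c(vals[[sc]], fn(set, weights))
        }
      }
    }
  }
  terms <- vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))
  if (all(is.na(terms)))
    stopf("every anchor was skipped in every term; no loss can be computed")
  lam <- c(weights$lambda1, weights$lambda2, weights$lambda3)
  total <- sum(lam * ifelse(is.na(terms), 0, terms))
  structure(list(total = total, amcl = terms[["amcl"]],
                 emcl = terms[["emcl"]], smcl = terms[["smcl"]],
                 skipped = skipped, n_anchors = B * length(mods)),
            class = "mercl_loss")
}

#' @export
print.mercl_loss <- function(x, ...) {
  cat(sprintf("MERCL loss %.5f (amcl %.5f | emcl %.5f | smcl %.5f; skipped %d/%d/%d)\n",
              x$total, x$amcl, x$emcl, x$smcl,
              x$skipped["amcl"], x$skipped["emcl"], x$skipped["smcl"]))
  invisible(x)
}

## ---- vectorized loss + analytic gradient (training path) -------------------
## Computes the same quantities as mercl_loss() (softened or literal mode)
## plus d(total)/d(z_m) for each modality; verified against the per-anchor
## path and numerical differentiation in the test suite.

mercl_loss_grad <- function(z_all, labels, weights = mercl_weights(),
                            energy_flags = NULL) {
  mods <- names(z_all)
  B <- nrow(z_all[[1]])
  tau <- weights$temperature
  present <- as_present(energy_flags, B)
  valid_of <- function(m) if (m == "audio") present else rep(TRUE, B)
  same <- outer(labels, labels, `==`)
  diag_excl <- !diag(TRUE, B)

  grads <- lapply(z_all, function(z) z * 0)
  per_anchor <- list(amcl = list(), emcl = list(), smcl = list())
  skipped <- c(amcl = 0L, emcl = 0L, smcl = 0L)

  ## d(per-anchor ratio loss)/d(s) for a row of scores split into pos/neg.
  ## Returns the score-gradient row (zeros where masked) given masks & scores.
  ratio_row_grad <- function(s, pmask, nmask) {
    if (weights$literal_mode) {
      num <- sum(s[pmask]); den <- num + sum(s[nmask])
      if (num <= 0 || den <= 0)
        stopf("literal-mode ratio is nonpositive; use the softened mode")
      g <- numeric(length(s))
      g[pmask] <- -(1 / num - 1 / den)
      g[nmask] <- 1 / den
      loss <- -log(num / den)
    } else {
      mx <- max(s[pmask | nmask])
      e <- exp((s - mx) / tau)
      SP <- sum(e[pmask]); SN <- sum(e[nmask])
      g <- numeric(length(s))
      g[pmask] <- (e[pmask] / (SP + SN) - e[pmask] / SP) / tau
      g[nmask] <- (e[nmask] / (SP + SN)) / tau
      loss <- log(SP + SN) - log(SP)
    }
    list(loss = loss, g = g)
  }

  ## ---- AMCL ----
  amcl_rows <- list()  # anchors with their score-grad rows per modality
  for (m in mods) {
    v <- valid_of(m)
    S <- tcrossprod(z_all[[m]])              # B x B similarities
    P <- same & diag_excl & matrix(v, B, B, byrow = TRUE)
    N <- (!same) & matrix(v, B, B, byrow = TRUE)
    G <- matrix(0, B, B)
    for (i in seq_len(B)) {
      if (!v[i] || !any(P[i, ])) { skipped["amcl"] <- skipped["amcl"] + 1L; next }
      r <- ratio_row_grad(S[i, ], P[i, ], N[i, ])
      per_anchor$amcl[[length(per_anchor$amcl) + 1L]] <- r$loss
      G[i, ] <- r$g
    }
    amcl_rows[[m]] <- G
  }
  n_am <- length(per_anchor$amcl)
  if (n_am > 0 && weights$lambda1 != 0) {
    for (m in mods) {
      G <- amcl_rows[[m]] * (weights$lambda1 / n_am)
      grads[[m]] <- grads[[m]] + (G + t(G)) %*% z_all[[m]]
    }
  }

  ## ---- EMCL ----
  emcl_rows <- list()
  for (m in mods) {
    others <- setdiff(mods, m)
    v_anchor <- valid_of(m)
    S <- lapply(others, function(mo) tcrossprod(z_all[[m]], z_all[[mo]]))
    names(S) <- others
    P <- lapply(others, function(mo)
      same & diag_excl & matrix(valid_of(mo), B, B, byrow = TRUE))
    N <- lapply(others, function(mo)
      (!same) & matrix(valid_of(mo), B, B, byrow = TRUE))
    names(P) <- others; names(N) <- others
    G <- lapply(others, function(mo) matrix(0, B, B))
    names(G) <- others
    for (i in seq_len(B)) {
      pmask <- c(P[[1]][i, ], P[[2]][i, ])
      if (!v_anchor[i] || !any(pmask)) {
        skipped["emcl"] <- skipped["emcl"] + 1L; next
      }
      s <- c(S[[1]][i, ], S[[2]][i, ])
      nmask <- c(N[[1]][i, ], N[[2]][i, ])
      r <- ratio_row_grad(s, pmask, nmask)
      per_anchor$emcl[[length(per_anchor$emcl) + 1L]] <- r$loss
      G[[1]][i, ] <- r$g[seq_len(B)]
      G[[2]][i, ] <- r$g[B + seq_len(B)]
    }
    emcl_rows[[m]] <- G
  }
  n_em <- length(per_anchor$emcl)
  if (n_em > 0 && weights$lambda2 != 0) {
    for (m in mods) {
      others <- setdiff(mods, m)
      for (mo in others) {
        G <- emcl_rows[[m]][[mo]] * (weights$lambda2 / n_em)
        grads[[m]] <- grads[[m]] + G %*% z_all[[mo]]
        grads[[mo]] <- grads[[mo]] + t(G) %*% z_all[[m]]
      }
    }
  }

  ## ---- SMCL ----
  smcl_pairs <- list()
  for (m in mods) {
    others <- setdiff(mods, m)
    v_anchor <- valid_of(m)
    for (i in seq_len(B)) {
      if (!v_anchor[i]) { skipped["smcl"] <- skipped["smcl"] + 1L; next }
      keep <- others[vapply(others, function(mo) valid_of(mo)[i], logical(1))]
      if (length(keep) == 0L) { skipped["smcl"] <- skipped["smcl"] + 1L; next }
      s <- vapply(keep, function(mo) sum(z_all[[m]][i, ] * z_all[[mo]][i, ]),
                  numeric(1))
      per_anchor$smcl[[length(per_anchor$smcl) + 1L]] <-
        0.5 * sum((s - weights$alpha)^2)
      smcl_pairs[[length(smcl_pairs) + 1L]] <-
        list(m = m, i = i, keep = keep, s = s)
    }
  }
  n_sm <- length(per_anchor$smcl)
  if (n_sm > 0 && weights$lambda3 != 0) {
    for (pr in smcl_pairs) {
      for (k in seq_along(pr$keep)) {
        mo <- pr$keep[k]
        g <- weights$lambda3 * (pr$s[k] - weights$alpha) / n_sm
        grads[[pr$m]][pr$i, ] <- grads[[pr$m]][pr$i, ] + g * z_all[[mo]][pr$i, ]
        grads[[mo]][pr$i, ] <- grads[[mo]][pr$i, ] + g * z_all[[pr$m]][pr$i, ]
      }
    }
  }

  terms <- c(amcl = if (n_am) mean(unlist(per_anchor$amcl)) else NA_real_,
             emcl = if (n_em) mean(unlist(per_anchor$emcl)) else NA_real_,
             smcl = if (n_sm) mean(unlist(per_anchor$smcl)) else NA_real_)
  if (all(is.na(terms)))
    stopf("every anchor was skipped in every term; no loss can be computed")
  lam <- c(weights$lambda1, weights$lambda2, weights$lambda3)
  total <- sum(lam * ifelse(is.na(terms), 0, terms))
  list(total = total, terms = terms, skipped = skipped, grads = grads)
}
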