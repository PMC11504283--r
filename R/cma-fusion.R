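# Pairwise cross-modal attention (CMA) fusion: six directed multi-head
# attention blocks between the modality pairs, pooled and concatenated for an
# MLP classifier head.

CMA_DIRECTIONS <- c("a_to_v", "v_to_a", "e_to_v", "v_to_e", "e_to_a", "a_to_e")

#' Initialize multi-head attention parameters
#'
#' Per-head query/key/value projections (stored packed as `D x (heads * d_k)`
#' matrices) and the output matrix `W_O` mapping the concatenated heads back
#' to width `D`. Weights are drawn from the current RNG stream.
#'
#' @param d Model width `D`.
#' @param n_heads Head count (default 4); `n_heads * d_k` must equal `D`.
#' @param d_k Per-head key width (default `D / n_heads`).
#' @return Parameter list (`Wq`, `Wk`, `Wv`, `Wo`, `n_heads`, `d_k`).
#' @export
mha_init <- function(d, n_heads = 4L, d_k = d %/% n_heads) {
  if (n_heads < 1L) stopf("`n_heads` must be >= 1")
  if (n_heads * d_k != d)
    stopf("`n_heads * d_k` (%d) must equal the model width D (%d)",
          n_heads * d_k, d)
  sd <- sqrt(1 / d)
  rnd <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  list(Wq = rnd(d, n_heads * d_k), Wk = rnd(d, n_heads * d_k),
       Wv = rnd(d, n_heads * d_k), Wo = rnd(n_heads * d_k, d),
       n_heads = as.integer(n_heads), d_k = as.integer(d_k))
}

## Forward with cache (single sample: Tq x D, Tk x D).
mha_fwd <- function(Xq, Xkv, p, raw_scores = FALSE) {
  H <- p$n_heads; dk <- p$d_k
  Q <- Xq %*% p$Wq
  K <- Xkv %*% p$Wk
  V <- Xkv %*% p$Wv
  Tq <- nrow(Xq)
  concat <- matrix(0, Tq, H * dk)
  heads <- vector("list", H)
  for (h in seq_len(H)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dk)
    A <- if (raw_scores) S else softmax_rows(S)
    concat[, idx] <- A %*% V[, idx, drop = FALSE]
    heads[[h]] <- list(A = A)
  }
  out <- concat %*% p$Wo
  list(out = out,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V,
                    concat = concat, heads = heads,
                    raw_scores = raw_scores))
}

## Backward: G is d(loss)/d(out), Tq x D.
mha_bwd <- function(G, cache, p) {
  H <- p$n_heads; dk <- p$d_k
  dWo <- crossprod(cache$concat, G)
  dConcat <- G %*% t(p$Wo)
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(H)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    A <- cache$heads[[h]]$A
    Vh <- cache$V[, idx, drop = FALSE]
    dH <- dConcat[, idx, drop = FALSE]
    dA <- tcrossprod(dH, Vh)
    dV[, idx] <- crossprod(A, dH)
    dS <- if (cache$raw_scores) dA else A * (dA - rowSums(dA * A))
    dS <- dS / sqrt(dk)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  list(dXq = dQ %*% t(p$Wq),
       dXkv = dK %*% t(p$Wk) + dV %*% t(p$Wv),
       grads = list(Wq = crossprod(cache$Xq, dQ),
                    Wk = crossprod(cache$Xkv, dK),
                    Wv = crossprod(cache$Xkv, dV),
                    Wo = dWo))
}

#' Multi-head attention between two sequences
#'
#' The first argument supplies queries, the second keys and values. Per head,
#' attention weights are the row-softmax of `Q K^T / sqrt(d_k)`; head outputs
#' are concatenated and mapped by `W_O`. `raw_scores = TRUE` skips the
#' softmax and uses the scaled dot products directly as weights (a study
#' variant; the default is standard multi-head attention).
#'
#' @param query_source `T_q x D` matrix.
#' @param kv_source `T_k x D` matrix.
#' @param params From [mha_init()].
#' @param raw_scores Skip the softmax over attention scores.
#' @return `T_q x D` matrix.
#' @export
multi_head_attention <- function(query_source, kv_source, params,
                                 raw_scores = FALSE) {
  d <- nrow(params$Wq)
  if (ncol(query_source) != d || ncol(kv_source) != d)
    stopf("attention expects width %d, got %d (query) and %d (key/value)",
          d, ncol(query_source), ncol(kv_source))
  if (nrow(query_source) < 1L || nrow(kv_source) < 1L)
    stopf("query and key/value sequences must be nonempty")
  mha_fwd(query_source, kv_source, params, raw_scores)$out
}

#' Attention weight matrices of one call
#'
#' Diagnostic accessor: the per-head row-stochastic attention matrices for a
#' query/key-value pair.
#'
#' @inheritParams multi_head_attention
#' @return List of `T_q x T_k` matrices, one per head.
#' @export
attention_weights <- function(query_source, kv_source, params,
                              raw_scores = FALSE) {
  lapply(mha_fwd(query_source, kv_source, params, raw_scores)$cache$heads,
         `[[`, "A")
}

#' Initialize the six directed cross-modal attention blocks
#'
#' Independent parameters per direction, in the fixed order
#' `a_to_v, v_to_a, e_to_v, v_to_e, e_to_a, a_to_e`.
#'
#' @param d Model width `D`.
#' @param n_heads Heads per block (default 4).
#' @return Named list of six [mha_init()] parameter sets.
#' @export
cma_init <- function(d, n_heads = 4L) {
  ps <- lapply(CMA_DIRECTIONS, function(dir) mha_init(d, n_heads))
  names(ps) <- CMA_DIRECTIONS
  ps
}

## Query / key-value wiring per direction: the direction x_to_y means
## "attend from modality y's queries onto modality x's keys/values".
cma_wiring <- function() {
  list(a_to_v = c(q = "video", kv = "audio"),
       v_to_a = c(q = "audio", kv = "video"),
       e_to_v = c(q = "video", kv = "eeg"),
       v_to_e = c(q = "eeg", kv = "video"),
       e_to_a = c(q = "audio", kv = "eeg"),
       a_to_e = c(q = "eeg", kv = "audio"))
}

pool_rows <- function(M, pooling) {
  switch(pooling,
         mean = colMeans(M),
         last = M[nrow(M), ],
         max = apply(M, 2L, max))
}

## Internal batched forward with caches. h: named list of (B, T_m, D) arrays.
## The Q/K/V projections and the output map run as whole-batch matrix
## products ((B*T) x D layout); only the per-sample, per-head attention
## matrices stay in loops. For mean pooling the output projection commutes
## with the pooling, so it is applied to the time-pooled concatenation.
cma_fwd_batch <- function(h, params, pooling = "mean", raw_scores = FALSE) {
  wiring <- cma_wiring()
  B <- dim(h$video)[1]
  D <- dim(h$video)[3]
  pooled <- list(); caches <- list()
  for (dir in CMA_DIRECTIONS) {
    w <- wiring[[dir]]
    p <- params[[dir]]
    H <- p$n_heads; dk <- p$d_k
    Tq <- dim(h[[w["q"]]])[2]; Tk <- dim(h[[w["kv"]]])[2]
    Xq <- seq_to_mat(h[[w["q"]]])
    Xkv <- seq_to_mat(h[[w["kv"]]])
    Q <- Xq %*% p$Wq
    K <- Xkv %*% p$Wk
    V <- Xkv %*% p$Wv
    concat <- matrix(0, B * Tq, H * dk)
    A_all <- vector("list", B)
    for (b in seq_len(B)) {
      rq <- (b - 1L) * Tq + seq_len(Tq)
      rk <- (b - 1L) * Tk + seq_len(Tk)
      Ab <- vector("list", H)
      for (hd in seq_len(H)) {
        idx <- (hd - 1L) * dk + seq_len(dk)
        S <- tcrossprod(Q[rq, idx, drop = FALSE],
                        K[rk, idx, drop = FALSE]) / sqrt(dk)
        A <- if (raw_scores) S else softmax_rows(S)
        concat[rq, idx] <- A %*% V[rk, idx, drop = FALSE]
        Ab[[hd]] <- A
      }
      A_all[[b]] <- Ab
    }
    pc <- switch(pooling,
                 mean = rowsum(concat, rep(seq_len(B), each = Tq)) / Tq,
                 last = concat[seq_len(B) * Tq, , drop = FALSE],
                 max = NULL)
    if (pooling == "max") {
      out_all <- concat %*% p$Wo
      grp <- rep(seq_len(B), each = Tq)
      pooled[[dir]] <- do.call(rbind, lapply(split.data.frame(out_all, grp),
                                             function(m) apply(m, 2L, max)))
      pc <- NULL
    } else {
      pooled[[dir]] <- pc %*% p$Wo
    }
    caches[[dir]] <- list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V,
                          A = A_all, pooled_concat = pc, Tq = Tq, Tk = Tk,
                          raw_scores = raw_scores)
  }
  names(pooled) <- CMA_DIRECTIONS
  names(caches) <- CMA_DIRECTIONS
  concat <- do.call(cbind, pooled)
  list(pooled = pooled, concat = concat, caches = caches, pooling = pooling,
       B = B)
}

## Backward from d(loss)/d(concat) (B x 6D) to parameter grads and, when
## requested, gradients on the input representations.
cma_bwd_batch <- function(Gconcat, fw, h, params, need_input_grads = FALSE) {
  wiring <- cma_wiring()
  B <- nrow(Gconcat)
  D <- ncol(Gconcat) %/% 6L
  grads <- list()
  dh <- if (need_input_grads) lapply(h, function(a) a * 0) else NULL
  for (k in seq_along(CMA_DIRECTIONS)) {
    dir <- CMA_DIRECTIONS[k]
    w <- wiring[[k]]
    p <- params[[dir]]
    cc <- fw$caches[[dir]]
    H <- p$n_heads; dk <- p$d_k
    Tq <- cc$Tq; Tk <- cc$Tk
    Gp <- Gconcat[, (k - 1L) * D + seq_len(D), drop = FALSE]
    if (is.null(cc$pooled_concat))
      stopf("backward not implemented for pooling 'max'")
    dWo <- crossprod(cc$pooled_concat, Gp)
    dPc <- Gp %*% t(p$Wo)                  # B x (H*dk)
    dQ <- matrix(0, B * Tq, H * dk)
    dK <- matrix(0, B * Tk, H * dk)
    dV <- matrix(0, B * Tk, H * dk)
    for (b in seq_len(B)) {
      rq <- (b - 1L) * Tq + seq_len(Tq)
      rk <- (b - 1L) * Tk + seq_len(Tk)
      for (hd in seq_len(H)) {
        idx <- (hd - 1L) * dk + seq_len(dk)
        ## d(concat rows) for this sample/head from the pooling adjoint
        dH <- if (fw$pooling == "mean")
          matrix(dPc[b, idx] / Tq, Tq, dk, byrow = TRUE)
        else rbind(matrix(0, Tq - 1L, dk),
                   dPc[b, idx])
        A <- cc$A[[b]][[hd]]
        Vh <- cc$V[rk, idx, drop = FALSE]
        dA <- tcrossprod(dH, Vh)
        dV[rk, idx] <- crossprod(A, dH)
        dS <- if (cc$raw_scores) dA else A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(dk)
        dQ[rq, idx] <- dS %*% cc$K[rk, idx, drop = FALSE]
        dK[rk, idx] <- crossprod(dS, cc$Q[rq, idx, drop = FALSE])
      }
    }
    grads[[dir]] <- list(Wq = crossprod(cc$Xq, dQ),
                         Wk = crossprod(cc$Xkv, dK),
                         Wv = crossprod(cc$Xkv, dV),
                         Wo = dWo)
    if (need_input_grads) {
      dXq <- dQ %*% t(p$Wq)
      dXkv <- dK %*% t(p$Wk) + dV %*% t(p$Wv)
      dh[[w["q"]]] <- dh[[w["q"]]] + mat_to_seq(dXq, B, Tq)
      dh[[w["kv"]]] <- dh[[w["kv"]]] + mat_to_seq(dXkv, B, Tk)
    }
  }
  names(grads) <- CMA_DIRECTIONS
  list(grads = grads, dh = dh)
}

#' Pairwise cross-modal attention fusion
#'
#' Computes the six directed attention results between the modality pairs --
#' in each direction the first-named modality supplies keys/values and the
#' second supplies queries (`a_to_v` attends video queries onto audio) --
#' pools each result over its query-time axis and concatenates them in the
#' fixed order `a_to_v, v_to_a, e_to_v, v_to_e, e_to_a, a_to_e`.
#'
#' @param h_v,h_a,h_e Spatiotemporal representations: `T_m x D` matrices (one
#'   sample) or `B x T_m x D` arrays, sharing the feature width `D`.
#' @param params From [cma_init()].
#' @param pooling `"mean"` (default), `"last"` or `"max"` over query time.
#' @param raw_scores Study variant without the attention softmax.
#' @return Object of class `fusion_output`: `r` (named list of six `B x D`
#'   pooled results), `concatenated` (`B x 6D`) and `directions`.
#' @export
pairwise_cma <- function(h_v, h_a, h_e, params,
                         pooling = c("mean", "last", "max"),
                         raw_scores = FALSE) {
  pooling <- match.arg(pooling)
  if (is.null(h_v) || is.null(h_a) || is.null(h_e))
    stopf("fusion requires all three modalities")
  up <- function(x) if (is.matrix(x)) array(x, c(1L, nrow(x), ncol(x))) else x
  h <- list(video = up(h_v), audio = up(h_a), eeg = up(h_e))
  D <- unique(vapply(h, function(a) dim(a)[3], numeric(1)))
  if (length(D) != 1L)
    stopf("all modalities must share the feature width D")
  fw <- cma_fwd_batch(h, params, pooling, raw_scores)
  structure(list(r = fw$pooled, concatenated = fw$concat,
                 directions = CMA_DIRECTIONS, pooling = pooling),
            class = "fusion_output")
}

#' Initialize the MLP classifier head
#'
#' One hidden layer with ReLU and dropout, then a linear layer and softmax.
#'
#' @param d_in Input width (6D for the fused vector).
#' @param n_classes Number of emotion classes.
#' @param hidden Hidden width (default 256).
#' @return Parameter list.
#' @export
classifier_init <- function(d_in, n_classes, hidden = 256L) {
  mlp_init(d_in, hidden, n_classes)
}

#' Classify fused representations
#'
#' @param fused A `fusion_output` (or a `B x d_in` matrix).
#' @param params From [classifier_init()].
#' @return Object of class `mercl_prediction`: `probs` (rows on the
#'   probability simplex), `logits` and `label_idx` (1-based argmax).
#' @export
classify <- function(fused, params) {
  X <- if (inherits(fused, "fusion_output")) fused$concatenated else fused
  if (ncol(X) != nrow(params$fc1$W))
    stopf("classifier expects width %d, got %d", nrow(params$fc1$W), ncol(X))
  logits <- mlp_fwd(X, params, dropout = 0, train = FALSE)$logits
  probs <- softmax_rows(logits)
  structure(list(probs = probs, logits = logits,
                 label_idx = max.col(probs, ties.method = "first")),
            class = "mercl_prediction")
}
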