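# Neural-network primitives with hand-written forward and backward passes.
# Batched sequences are stored as (B*T) x D matrices, rows grouped by sample
# with time running fastest, so convolutions become shifted matrix products
# and all heavy lifting goes through BLAS.

## ---- parameter trees ------------------------------------------------------

## Apply `f` elementwise over parallel nested lists of arrays (NULL passes
## through, so optional parameters like shortcut projections are transparent).
tree_map <- function(f, ...) {
  trees <- list(...)
  x <- trees[[1]]
  if (is.null(x)) return(NULL)
  if (is.list(x)) {
    out <- lapply(seq_along(x), function(i)
      do.call(tree_map, c(list(f), lapply(trees, function(tr) tr[[i]]))))
    names(out) <- names(x)
    return(out)
  }
  do.call(f, trees)
}

tree_zeros <- function(params) tree_map(function(p) p * 0, params)

tree_add <- function(a, b) tree_map(`+`, a, b)

## Sum of squares over a parameter tree (used for NaN/divergence checks and
## freeze checksums).
tree_sumsq <- function(params) {
  s <- 0
  walk <- function(x) {
    if (is.null(x)) return(invisible(NULL))
    if (is.list(x)) { lapply(x, walk); return(invisible(NULL)) }
    s <<- s + sum(x^2)
    invisible(NULL)
  }
  walk(params)
  s
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(params) list(m = tree_zeros(params),
                                   v = tree_zeros(params), t = 0L)

## The recursion is driven by the gradient tree, matched to parameters by
## name: parameter entries without a gradient (metadata like head counts,
## absent shortcuts) are left untouched.
adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  rec <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(g)) {
      keys <- if (is.null(names(g))) seq_along(g) else names(g)
      for (k in keys) {
        r <- rec(p[[k]], g[[k]], m[[k]], v[[k]])
        p[k] <- list(r$p); m[k] <- list(r$m); v[k] <- list(r$v)
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(p = p - lr * (m / c1) / (sqrt(v / c2) + eps), m = m, v = v)
  }
  r <- rec(params, grads, st$m, st$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = st$t))
}

## ---- elementary layers ----------------------------------------------------

nn_linear_init <- function(d_in, d_out, bias = TRUE) {
  sd <- sqrt(2 / (d_in + d_out))
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
       b = if (bias) numeric(d_out) else NULL)
}

nn_linear_fwd <- function(X, p) {
  out <- X %*% p$W
  if (!is.null(p$b)) out <- sweep(out, 2L, p$b, `+`)
  list(out = out, X = X)
}

nn_linear_bwd <- function(G, cache, p) {
  list(dX = G %*% t(p$W),
       grads = list(W = crossprod(cache$X, G),
                    b = if (!is.null(p$b)) colSums(G) else NULL))
}

elu_fwd <- function(x, a = 1) ifelse(x > 0, x, a * (exp(x) - 1))
elu_bwd <- function(G, out, a = 1) G * ifelse(out > 0, 1, out + a)

relu_fwd <- function(x) pmax(x, 0)

dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - rate), nrow(X)) / (1 - rate)
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(G, mask) if (is.null(mask)) G else G * mask

bn_init <- function(d) list(gamma = rep(1, d), beta = numeric(d))
bn_state_init <- function(d) list(mean = numeric(d), var = rep(1, d))

bn_fwd <- function(X, p, state, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2L, mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, mu), 2L, inv_sd, `*`)
  out <- sweep(sweep(xhat, 2L, p$gamma, `*`), 2L, p$beta, `+`)
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, train = train),
       state = state)
}

bn_bwd <- function(G, cache, p) {
  dgamma <- colSums(G * cache$xhat)
  dbeta <- colSums(G)
  Gx <- sweep(G, 2L, p$gamma, `*`)
  if (cache$train) {
    n <- nrow(G)
    dX <- sweep(Gx - matrix(colMeans(Gx), n, ncol(G), byrow = TRUE) -
                  cache$xhat * matrix(colMeans(Gx * cache$xhat), n, ncol(G),
                                      byrow = TRUE),
                2L, cache$inv_sd, `*`)
  } else {
    dX <- sweep(Gx, 2L, cache$inv_sd, `*`)
  }
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- causal shifted-row machinery for dilated convolutions ---------------

## Shift each sample's rows by `s` time steps (positive s = delay, zeros fill
## the vacated steps). Rows are (B*T) x D with time fastest.
shift_rows <- function(X, B, T, s) {
  if (s == 0) return(X)
  t <- rep.int(seq_len(T), B)
  src_t <- t - s
  valid <- src_t >= 1L & src_t <= T
  out <- matrix(0, nrow(X), ncol(X))
  out[valid, ] <- X[which(valid) - s, , drop = FALSE]
  out
}

dconv_init <- function(k, d_in, d_out) {
  sd <- sqrt(2 / (k * d_in + d_out))
  list(W = lapply(seq_len(k),
                  function(i) matrix(stats::rnorm(d_in * d_out, sd = sd),
                                     d_in, d_out)),
       b = numeric(d_out))
}

dconv_fwd <- function(X, B, T, p, d) {
  out <- matrix(0, nrow(X), length(p$b))
  for (i in seq_along(p$W))
    out <- out + shift_rows(X, B, T, d * (i - 1L)) %*% p$W[[i]]
  out <- sweep(out, 2L, p$b, `+`)
  list(out = out, X = X)
}

dconv_bwd <- function(G, cache, p, d, B, T) {
  dX <- matrix(0, nrow(G), nrow(p$W[[1]]))
  dW <- vector("list", length(p$W))
  for (i in seq_along(p$W)) {
    s <- d * (i - 1L)
    dW[[i]] <- crossprod(shift_rows(cache$X, B, T, s), G)
    dX <- dX + shift_rows(G %*% t(p$W[[i]]), B, T, -s)
  }
  list(dX = dX, grads = list(W = dW, b = colSums(G)))
}

## ---- softmax / cross-entropy ---------------------------------------------

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## y: 1-based class indices. Returns mean cross-entropy and d(loss)/d(logits).
ce_fwd_bwd <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, grad = G / n, probs = P)
}

## ---- MLP classifier head --------------------------------------------------

mlp_init <- function(d_in, hidden, n_classes) {
  list(fc1 = nn_linear_init(d_in, hidden),
       fc2 = nn_linear_init(hidden, n_classes))
}

mlp_fwd <- function(X, p, dropout = 0, train = FALSE) {
  f1 <- nn_linear_fwd(X, p$fc1)
  h <- relu_fwd(f1$out)
  dp <- dropout_fwd(h, dropout, train)
  f2 <- nn_linear_fwd(dp$out, p$fc2)
  list(logits = f2$out,
       cache = list(f1 = f1, h = h, dp = dp, f2 = f2))
}

mlp_bwd <- function(G, cache, p) {
  b2 <- nn_linear_bwd(G, cache$f2, p$fc2)
  Gh <- dropout_bwd(b2$dX, cache$dp$mask)
  Gh <- Gh * (cache$h > 0)
  b1 <- nn_linear_bwd(Gh, cache$f1, p$fc1)
  list(dX = b1$dX, grads = list(fc1 = b1$grads, fc2 = b2$grads))
}
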