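# Numeric-gradient verification of the hand-written backward passes. Each
# check compares the analytic gradient of sum(out * R) against central finite
# differences on a few parameter entries.

num_grad <- function(f, eps = 1e-6) function(set_eps) {
  (f(set_eps(eps)) - f(set_eps(-eps))) / (2 * eps)
}

test_that("residual TCN backward matches finite differences", {
  set.seed(200)
  cfg <- tcn_config(channels = 6L, dropout_rate = 0,
                    dilation_rates = c(1L, 2L), n_blocks = 2L)
  B <- 3L; T <- 10L; Din <- 4L
  p <- tcn_init(Din, cfg)
  st <- tcn_state_init(cfg)
  X <- mercl:::seq_to_mat(array(rnorm(B * T * Din), c(B, T, Din)))
  R <- matrix(rnorm(B * T * cfg$channels), B * T)
  fw <- mercl:::tcn_fwd(X, B, T, p, st, cfg, train = TRUE)
  bw <- mercl:::tcn_bwd(R, fw$caches, p, cfg, B, T)
  loss <- function(pp, xx = X)
    sum(mercl:::tcn_fwd(xx, B, T, pp, st, cfg, train = TRUE)$out * R)

  probes <- list(
    list(get = function() bw$grads$blocks[[1]]$conv1$W[[2]][2, 3],
         set = function(e) { q <- p; q$blocks[[1]]$conv1$W[[2]][2, 3] <-
           q$blocks[[1]]$conv1$W[[2]][2, 3] + e; q }),
    list(get = function() bw$grads$blocks[[2]]$conv1$b[5],
         set = function(e) { q <- p; q$blocks[[2]]$conv1$b[5] <-
           q$blocks[[2]]$conv1$b[5] + e; q }),
    list(get = function() bw$grads$blocks[[2]]$bn1$gamma[4],
         set = function(e) { q <- p; q$blocks[[2]]$bn1$gamma[4] <-
           q$blocks[[2]]$bn1$gamma[4] + e; q }),
    list(get = function() bw$grads$blocks[[1]]$bn1$beta[2],
         set = function(e) { q <- p; q$blocks[[1]]$bn1$beta[2] <-
           q$blocks[[1]]$bn1$beta[2] + e; q }),
    list(get = function() bw$grads$blocks[[1]]$shortcut$W[1, 2],
         set = function(e) { q <- p; q$blocks[[1]]$shortcut$W[1, 2] <-
           q$blocks[[1]]$shortcut$W[1, 2] + e; q }))
  for (pr in probes) {
    eps <- 1e-6
    num <- (loss(pr$set(eps)) - loss(pr$set(-eps))) / (2 * eps)
    expect_equal(pr$get(), num, tolerance = 1e-5)
  }
  # input gradient
  eps <- 1e-6
  X1 <- X; X1[7, 2] <- X1[7, 2] + eps
  X2 <- X; X2[7, 2] <- X2[7, 2] - eps
  expect_equal(bw$dX[7, 2], (loss(p, X1) - loss(p, X2)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("attention backward matches finite differences", {
  set.seed(201)
  D <- 8L
  p <- mha_init(D, 2L)
  q <- matrix(rnorm(5 * D), 5); kv <- matrix(rnorm(7 * D), 7)
  R <- matrix(rnorm(5 * D), 5)
  fw <- mercl:::mha_fwd(q, kv, p)
  bw <- mercl:::mha_bwd(R, fw$cache, p)
  loss <- function(pp, qq = q, kk = kv) sum(mercl:::mha_fwd(qq, kk, pp)$out * R)
  eps <- 1e-6
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    p1 <- p; p1[[nm]][3, 5] <- p1[[nm]][3, 5] + eps
    p2 <- p; p2[[nm]][3, 5] <- p2[[nm]][3, 5] - eps
    expect_equal(bw$grads[[nm]][3, 5], (loss(p1) - loss(p2)) / (2 * eps),
                 tolerance = 1e-5, info = nm)
  }
  q1 <- q; q1[2, 3] <- q1[2, 3] + eps; q2 <- q; q2[2, 3] <- q2[2, 3] - eps
  expect_equal(bw$dXq[2, 3], (loss(p, q1) - loss(p, q2)) / (2 * eps),
               tolerance = 1e-5)
  k1 <- kv; k1[4, 1] <- k1[4, 1] + eps; k2 <- kv; k2[4, 1] <- k2[4, 1] - eps
  expect_equal(bw$dXkv[4, 1], (loss(p, q, k1) - loss(p, q, k2)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("batched fusion backward matches finite differences", {
  set.seed(202)
  B <- 2L; D <- 8L
  h <- list(video = array(rnorm(B * 3 * D), c(B, 3, D)),
            audio = array(rnorm(B * 4 * D), c(B, 4, D)),
            eeg = array(rnorm(B * 2 * D), c(B, 2, D)))
  params <- cma_init(D, 2L)
  R <- matrix(rnorm(B * 6 * D), B)
  loss <- function(hh, pp = params)
    sum(mercl:::cma_fwd_batch(hh, pp, "mean")$concat * R)
  fw <- mercl:::cma_fwd_batch(h, params, "mean")
  bw <- mercl:::cma_bwd_batch(R, fw, h, params, need_input_grads = TRUE)
  eps <- 1e-6
  p1 <- params; p1$e_to_a$Wq[3, 5] <- p1$e_to_a$Wq[3, 5] + eps
  p2 <- params; p2$e_to_a$Wq[3, 5] <- p2$e_to_a$Wq[3, 5] - eps
  expect_equal(bw$grads$e_to_a$Wq[3, 5],
               (loss(h, p1) - loss(h, p2)) / (2 * eps), tolerance = 1e-5)
  h1 <- h; h1$audio[2, 3, 6] <- h1$audio[2, 3, 6] + eps
  h2 <- h; h2$audio[2, 3, 6] <- h2$audio[2, 3, 6] - eps
  expect_equal(bw$dh$audio[2, 3, 6], (loss(h1) - loss(h2)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("cross-entropy head backward matches finite differences", {
  set.seed(203)
  p <- mercl:::mlp_init(6L, 5L, 3L)
  X <- matrix(rnorm(4 * 6), 4)
  y <- c(1L, 3L, 2L, 1L)
  fw <- mercl:::mlp_fwd(X, p)
  ce <- mercl:::ce_fwd_bwd(fw$logits, y)
  bw <- mercl:::mlp_bwd(ce$grad, fw$cache, p)
  loss <- function(pp)
    mercl:::ce_fwd_bwd(mercl:::mlp_fwd(X, pp)$logits, y)$loss
  eps <- 1e-6
  p1 <- p; p1$fc1$W[2, 3] <- p1$fc1$W[2, 3] + eps
  p2 <- p; p2$fc1$W[2, 3] <- p2$fc1$W[2, 3] - eps
  expect_equal(bw$grads$fc1$W[2, 3], (loss(p1) - loss(p2)) / (2 * eps),
               tolerance = 1e-5)
  p1 <- p; p1$fc2$b[2] <- p1$fc2$b[2] + eps
  p2 <- p; p2$fc2$b[2] <- p2$fc2$b[2] - eps
  expect_equal(bw$grads$fc2$b[2], (loss(p1) - loss(p2)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("Adam leaves parameters without gradients untouched and steps the rest", {
  p <- list(a = matrix(1, 2, 2), meta = 7L, b = list(W = rep(0.5, 3)))
  g <- list(a = matrix(1, 2, 2), b = list(W = c(1, -1, 0)))
  st <- mercl:::adam_init(p)
  out <- mercl:::adam_step(p, g, st, lr = 0.1)
  expect_identical(out$params$meta, 7L)
  expect_true(all(out$params$a < p$a))        # positive grad -> decrease
  expect_lt(out$params$b$W[1], 0.5)
  expect_gt(out$params$b$W[2], 0.5)
  expect_equal(out$params$b$W[3], 0.5)
})
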