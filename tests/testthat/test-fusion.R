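test_that("identical key rows give uniform attention and mean-of-values output", {
  D <- 4
  p <- mha_init(D, 1L)
  p$Wo <- diag(D)
  q <- matrix(rnorm(3 * D), 3, D)
  kv <- matrix(rep(rnorm(D), each = 5), 5, D)  # identical rows
  aw <- attention_weights(q, kv, p)[[1]]
  expect_equal(aw, matrix(1 / 5, 3, 5), tolerance = 1e-12)
  out <- multi_head_attention(q, kv, p)
  vmean <- colMeans(kv %*% p$Wv)
  for (r in 1:3) expect_equal(out[r, ], vmean, tolerance = 1e-12)
})

test_that("attention weight rows sum to one", {
  set.seed(30)
  p <- mha_init(12L, 3L)
  aw <- attention_weights(matrix(rnorm(60), 5), matrix(rnorm(96), 8), p)
  for (A in aw) expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-6)
})

test_that("attention matches a brute-force per-row oracle", {
  brute_mha <- function(Xq, Xkv, p) {
    H <- p$n_heads; dk <- p$d_k
    concat <- matrix(0, nrow(Xq), H * dk)
    for (h in seq_len(H)) {
      idx <- (h - 1L) * dk + seq_len(dk)
      for (t in seq_len(nrow(Xq))) {
        q <- drop(Xq[t, ] %*% p$Wq[, idx])
        scores <- numeric(nrow(Xkv))
        for (u in seq_len(nrow(Xkv)))
          scores[u] <- sum(q * drop(Xkv[u, ] %*% p$Wk[, idx])) / sqrt(dk)
        a <- exp(scores - max(scores)); a <- a / sum(a)
        acc <- numeric(dk)
        for (u in seq_len(nrow(Xkv)))
          acc <- acc + a[u] * drop(Xkv[u, ] %*% p$Wv[, idx])
        concat[t, idx] <- acc
      }
    }
    concat %*% p$Wo
  }
  set.seed(31)
  for (i in 1:50) {
    D <- 8L
    heads <- sample(c(1L, 2L, 4L), 1)
    p <- mha_init(D, heads)
    Xq <- matrix(rnorm(sample(1:5, 1) * D), ncol = D)
    Xkv <- matrix(rnorm(sample(1:6, 1) * D), ncol = D)
    got <- multi_head_attention(Xq, Xkv, p)
    want <- brute_mha(Xq, Xkv, p)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("pairwise fusion has six directions with the contracted wiring", {
  set.seed(32)
  D <- 8L
  params <- cma_init(D, 2L)
  h_v <- matrix(rnorm(4 * D), 4); h_a <- matrix(rnorm(6 * D), 6)
  h_e <- matrix(rnorm(2 * D), 2)
  fo <- pairwise_cma(h_v, h_a, h_e, params)
  expect_s3_class(fo, "fusion_output")
  expect_length(fo$r, 6L)
  expect_equal(fo$directions,
               c("a_to_v", "v_to_a", "e_to_v", "v_to_e", "e_to_a", "a_to_e"))
  expect_equal(ncol(fo$concatenated), 6L * D)
  expect_error(pairwise_cma(h_v, NULL, h_e, params), "all three")
  # directed pair asymmetry: a->v and v->a differ for distinct inputs
  shared <- mha_init(D, 2L)
  p_shared <- lapply(fo$directions, function(d) shared)
  names(p_shared) <- fo$directions
  fo2 <- pairwise_cma(h_v, h_a, h_e, p_shared)
  expect_gt(max(abs(fo2$r$a_to_v - fo2$r$v_to_a)), 1e-3)
  # identical representations + shared parameters collapse symmetric pairs
  fo3 <- pairwise_cma(h_v, h_v, h_v, p_shared)
  expect_equal(fo3$r$a_to_v, fo3$r$e_to_v, tolerance = 1e-12)
  expect_equal(fo3$r$v_to_a, fo3$r$e_to_a, tolerance = 1e-12)
})

test_that("uniform attention makes pooled outputs invariant to key/value order", {
  set.seed(33)
  D <- 6L
  p <- mha_init(D, 1L)
  p$Wq <- matrix(0, D, D)  # zero queries -> constant scores -> uniform rows
  q <- matrix(rnorm(3 * D), 3)
  kv <- matrix(rnorm(5 * D), 5)
  a <- colMeans(multi_head_attention(q, kv, p))
  b <- colMeans(multi_head_attention(q, kv[sample(5), ], p))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the raw-scores study variant skips the softmax", {
  set.seed(34)
  D <- 4L
  p <- mha_init(D, 1L)
  q <- matrix(rnorm(2 * D), 2); kv <- matrix(rnorm(3 * D), 3)
  S <- (q %*% p$Wq) %*% t(kv %*% p$Wk) / sqrt(p$d_k)
  want <- (S %*% (kv %*% p$Wv)) %*% p$Wo
  expect_equal(multi_head_attention(q, kv, p, raw_scores = TRUE), want,
               tolerance = 1e-12)
})

test_that("the classifier returns a valid probability simplex", {
  set.seed(35)
  K <- 4L
  p <- classifier_init(12L, K, hidden = 8L)
  X <- matrix(rnorm(5 * 12), 5)
  pred <- classify(X, p)
  expect_equal(rowSums(pred$probs), rep(1, 5), tolerance = 1e-6)
  expect_true(all(pred$probs >= 0))
  expect_equal(pred$label_idx, max.col(pred$probs))
  # zero logits -> uniform probabilities
  p0 <- p
  p0$fc2$W[] <- 0; p0$fc2$b[] <- 0
  expect_equal(classify(X, p0)$probs, matrix(1 / K, 5, K), tolerance = 1e-12)
  # shifting all logits by a constant leaves probabilities unchanged
  p1 <- p; p1$fc2$b <- p1$fc2$b + 3.7
  expect_equal(classify(X, p1)$probs, pred$probs, tolerance = 1e-9)
  expect_error(classify(matrix(0, 2, 5), p), "width")
})

test_that("softmax probabilities match an explicit exp/normalize oracle", {
  set.seed(36)
  logits <- matrix(rnorm(100 * 5, sd = 3), 100)
  got <- mercl:::softmax_rows(logits)
  want <- t(apply(logits, 1L, function(r) exp(r) / sum(exp(r))))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("gradients flow to every fusion and classifier parameter", {
  set.seed(37)
  D <- 8L; B <- 4L
  h <- list(video = array(rnorm(B * 3 * D), c(B, 3, D)),
            audio = array(rnorm(B * 5 * D), c(B, 5, D)),
            eeg = array(rnorm(B * 2 * D), c(B, 2, D)))
  params <- cma_init(D, 2L)
  clf <- classifier_init(6L * D, 3L, hidden = 16L)
  fw <- mercl:::cma_fwd_batch(h, params, "mean")
  mf <- mercl:::mlp_fwd(fw$concat, clf)
  ce <- mercl:::ce_fwd_bwd(mf$logits, c(1L, 2L, 3L, 1L))
  mb <- mercl:::mlp_bwd(ce$grad, mf$cache, clf)
  cb <- mercl:::cma_bwd_batch(mb$dX, fw, h, params, need_input_grads = TRUE)
  for (dir in names(cb$grads))
    for (nm in c("Wq", "Wk", "Wv", "Wo"))
      expect_gt(sum(abs(cb$grads[[dir]][[nm]])), 0)
  for (nm in c("fc1", "fc2"))
    expect_gt(sum(abs(mb$grads[[nm]]$W)), 0)
  for (m in names(h)) expect_gt(sum(abs(cb$dh[[m]])), 0)
})
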