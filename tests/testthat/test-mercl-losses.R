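test_that("projection pools, maps and normalizes as contracted", {
  h <- matrix(c(1, 2, 3), 1, 3)  # single time step
  z <- project(h, diag(3), normalize = FALSE)
  expect_equal(drop(z), c(1, 2, 3))
  # normalized rows have unit norm
  set.seed(20)
  a <- array(rnorm(6 * 4 * 3), c(6, 4, 3))
  W <- matrix(rnorm(3 * 5), 3, 5)
  zn <- project(a, W)
  expect_equal(sqrt(rowSums(zn^2)), rep(1, 6), tolerance = 1e-6)
  # constant-in-time representation: mean pooling equals any slice
  const <- aperm(array(rnorm(12), c(3, 4, 5)), c(1, 3, 2))
  z1 <- project(const, diag(4), normalize = FALSE)
  expect_equal(z1, matrix(const[, 1, ], 3, 4), tolerance = 1e-12)
  expect_error(project(a, matrix(0, 7, 2)), "width")
})

test_that("pair construction follows the supervised definitions", {
  z <- random_embeddings(3, 4)
  labels <- c(0, 0, 1)
  s <- build_pairs(z, labels, 1, "video", "amcl")
  expect_equal(s$positives, z$video[2, , drop = FALSE])
  expect_equal(s$negatives, z$video[3, , drop = FALSE])

  s <- build_pairs(z, labels, 1, "video", "emcl")
  expect_equal(nrow(s$positives), 2L)  # 2N with N = 1
  expect_equal(nrow(s$negatives), 2L)
  expect_equal(s$positives, rbind(z$audio[2, ], z$eeg[2, ]),
               ignore_attr = TRUE)
  expect_equal(s$negatives, rbind(z$audio[3, ], z$eeg[3, ]),
               ignore_attr = TRUE)

  s <- build_pairs(z, labels, 2, "eeg", "smcl")
  expect_equal(nrow(s$positives), 2L)
  expect_equal(s$tags$pos, c("video", "audio"))
})

test_that("audio-energy exclusion removes flagged elements and skips anchors", {
  z <- random_embeddings(3, 4)
  labels <- c(0, 0, 1)
  flags <- c(TRUE, FALSE, TRUE)  # sample 2's audio is absent
  s <- build_pairs(z, labels, 2, "video", "smcl", flags)
  expect_equal(nrow(s$positives), 1L)
  expect_equal(s$tags$pos, "eeg")
  # audio anchor that is itself absent is skipped
  expect_null(build_pairs(z, labels, 2, "audio", "amcl", flags))
  # no positive available -> skip signal, not a crash
  expect_null(build_pairs(z, labels, 3, "video", "amcl"))
  # excluded audio removed from emcl candidate pool
  s <- build_pairs(z, labels, 1, "video", "emcl", flags)
  expect_equal(s$tags$pos, "eeg")  # only sample 2's eeg survives
})

test_that("literal-mode ratio loss is exact on separable fixtures and guards its domain", {
  P <- 4
  anchor <- c(1, 0, 0, 0)
  w <- mercl_weights(literal_mode = TRUE)
  set <- structure(list(anchor = anchor,
                        positives = matrix(anchor, 1),
                        negatives = matrix(c(0, 1, 0, 0), 1)),
                   class = "contrastive_set")
  expect_equal(amcl_loss(set, w), 0)  # -log(1 / (1 + 0))
  set$negatives <- matrix(-anchor, 1)  # similarity -1 -> denominator 0
  expect_error(amcl_loss(set, w), "softened")
})

test_that("softened ratio losses match a scalar brute-force oracle", {
  oracle <- function(sp, sn, tau) {
    -log(sum(exp(sp / tau)) / (sum(exp(sp / tau)) + sum(exp(sn / tau))))
  }
  set.seed(21)
  w <- mercl_weights(temperature = 0.1)
  for (i in 1:100) {
    P <- 6
    n_pos <- sample(1:5, 1); n_neg <- sample(0:5, 1)
    anchor <- rnorm(P); anchor <- anchor / sqrt(sum(anchor^2))
    pos <- matrix(rnorm(n_pos * P), n_pos)
    neg <- matrix(rnorm(n_neg * P), n_neg)
    pos <- pos / sqrt(rowSums(pos^2))
    if (n_neg > 0) neg <- neg / sqrt(rowSums(neg^2))
    set <- structure(list(anchor = anchor, positives = pos, negatives = neg),
                     class = "contrastive_set")
    expected <- oracle(pos %*% anchor, neg %*% anchor, 0.1)
    expect_equal(amcl_loss(set, w), expected, tolerance = 1e-6)
    expect_equal(emcl_loss(set, w), expected, tolerance = 1e-6)
    expect_gte(amcl_loss(set, w), 0)
  }
})

test_that("raising a negative similarity strictly raises the ratio loss", {
  w <- mercl_weights()
  anchor <- c(1, 0)
  mk <- function(s_neg) structure(
    list(anchor = anchor, positives = matrix(c(0.9, sqrt(1 - 0.81)), 1),
         negatives = matrix(c(s_neg, sqrt(1 - s_neg^2)), 1)),
    class = "contrastive_set")
  s_grid <- seq(-0.9, 0.9, by = 0.2)
  losses <- vapply(s_grid, function(s) amcl_loss(mk(s), w), numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("sample-wise alignment loss evaluates its quadratic form exactly", {
  anchor <- c(1, 0)
  at <- function(s) c(s, sqrt(1 - s^2))  # unit vector with given similarity
  expect_equal(smcl_loss(anchor, rbind(at(0.8), at(0.8)), alpha = 0.8), 0)
  expect_equal(smcl_loss(anchor, rbind(at(1.0), at(0.5)), alpha = 0.8), 0.065)
  s <- 0.3
  expect_equal(smcl_loss(anchor, at(s), alpha = 0.8), 0.5 * (s - 0.8)^2)
  expect_error(smcl_loss(anchor, matrix(0, 0, 2)), "no surviving")
})

test_that("the combined loss is the lambda-weighted sum of its terms", {
  z <- random_embeddings(8, 6, seed = 22)
  labels <- rep(0:1, each = 4)
  base <- mercl_loss(z, labels, mercl_weights(1, 1, 1))
  expect_equal(base$total, base$amcl + base$emcl + base$smcl)
  only_amcl <- mercl_loss(z, labels, mercl_weights(1, 0, 0))
  expect_equal(only_amcl$total, only_amcl$amcl)
  expect_equal(only_amcl$amcl, base$amcl)   # unweighted terms still logged
  expect_equal(only_amcl$smcl, base$smcl)
  wsum <- mercl_loss(z, labels, mercl_weights(0.5, 0.25, 0.25))
  expect_equal(wsum$total,
               0.5 * base$amcl + 0.25 * base$emcl + 0.25 * base$smcl)
  # arithmetic of the weighted sum on the documented example values
  expect_equal(sum(c(0.5, 0.25, 0.25) * c(0.4, 0.8, 0.2)), 0.45)
})

test_that("the combined loss is invariant to sample order", {
  z <- random_embeddings(7, 5, seed = 23)
  labels <- c(0, 1, 0, 2, 1, 2, 0)
  flags <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  a <- mercl_loss(z, labels, energy_flags = flags)
  b <- mercl_loss(lapply(z, function(m) m[perm, ]), labels[perm],
                  energy_flags = flags[perm])
  expect_equal(b$total, a$total, tolerance = 1e-10)
  expect_equal(unname(b$skipped), unname(a$skipped))
})

test_that("vectorized loss+gradient agrees with the per-anchor path and numeric gradients", {
  z <- random_embeddings(6, 5, seed = 24)
  labels <- c(0, 0, 1, 1, 2, 2)
  flags <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  w <- mercl_weights(0.7, 1.3, 0.5)
  ref <- mercl_loss(z, labels, w, flags)
  lg <- mercl:::mercl_loss_grad(z, labels, w, flags)
  expect_equal(lg$total, ref$total, tolerance = 1e-10)
  expect_equal(unname(lg$terms),
               unname(c(ref$amcl, ref$emcl, ref$smcl)), tolerance = 1e-10)
  expect_equal(unname(lg$skipped), unname(ref$skipped))
  eps <- 1e-6
  for (m in names(z)) {
    num <- matrix(0, 2, ncol(z[[m]]))
    for (i in 1:2) for (j in seq_len(ncol(z[[m]]))) {
      zp <- z; zp[[m]][i, j] <- zp[[m]][i, j] + eps
      zm <- z; zm[[m]][i, j] <- zm[[m]][i, j] - eps
      num[i, j] <- (mercl_loss(zp, labels, w, flags)$total -
                      mercl_loss(zm, labels, w, flags)$total) / (2 * eps)
    }
    expect_equal(lg$grads[[m]][1:2, ], num, tolerance = 1e-6)
  }
})

test_that("a gradient step on the combined loss decreases it for small enough steps", {
  z <- random_embeddings(8, 6, seed = 25)
  labels <- rep(0:3, 2)
  w <- mercl_weights()
  lg <- mercl:::mercl_loss_grad(z, labels, w)
  for (step in c(1e-2, 1e-3)) {
    z2 <- mapply(function(m, g) m - step * g, z, lg$grads, SIMPLIFY = FALSE)
    if (mercl_loss(z2, labels, w)$total < lg$total) break
  }
  expect_lt(mercl_loss(z2, labels, w)$total, lg$total)
})

test_that("weights are validated", {
  expect_error(mercl_weights(0, 0, 0), "not all zero")
  expect_error(mercl_weights(-1, 1, 1), "nonnegative")
  expect_error(mercl_weights(alpha = 1.5), "alpha")
  expect_error(mercl_weights(temperature = 0), "temperature")
})
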