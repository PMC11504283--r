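test_that("accuracy and F1 follow the confusion-count definitions", {
  m <- metrics_from_counts(tp = 3, tn = 5, fp = 1, fn = 1)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)
  expect_error(metrics_from_counts(-1, 0, 0, 0), "nonnegative")

  perfect <- compute_metrics(c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1_macro, 1)

  # class 2 never occurs in truth or prediction of this 3-class coding
  m2 <- compute_metrics(c(0, 0, 1, 1), c(0, 1, 1, 2))
  row2 <- m2$per_class[m2$per_class$class == 2, ]
  expect_equal(row2$f1, 0)
  expect_false(row2$degenerate)  # fn > 0: missed, not absent
  m3 <- compute_metrics(factor(c("a", "a"), levels = c("a", "b")),
                        factor(c("a", "a"), levels = c("a", "b")))
  expect_equal(m3$accuracy, 1)
  expect_error(compute_metrics(integer(0), integer(0)), "empty")
  expect_error(compute_metrics(1:3, 1:4), "length")
})

test_that("macro F1 averages one-vs-rest F1 over classes", {
  pred <- c(0, 0, 1, 1, 1, 2)
  true <- c(0, 1, 1, 1, 2, 2)
  m <- compute_metrics(pred, true)
  f1_by_hand <- mean(c(
    metrics_from_counts(1, 4, 1, 0)$f1,   # class 0
    metrics_from_counts(2, 2, 1, 1)$f1,   # class 1
    metrics_from_counts(1, 4, 0, 1)$f1))  # class 2
  expect_equal(m$f1_macro, f1_by_hand)
  expect_equal(m$accuracy, 4 / 6)
})

test_that("pre-training reduces the contrastive loss deterministically", {
  feats <- tiny_features()
  idx <- seq_len(32)
  sub <- mercl:::features_subset(feats, idx)
  cfg <- tiny_config(pretrain_epochs = 2L)
  enc <- pretrain(sub, cfg)
  log1 <- tidy(enc)
  expect_equal(nrow(log1), 2L)
  expect_lt(log1$total[2], log1$total[1])
  # same seed -> identical loss curves
  enc2 <- pretrain(sub, cfg)
  expect_identical(tidy(enc2), log1)
  expect_identical(enc2$params, enc$params)
})

test_that("zeroed loss weights mask terms but keep them logged", {
  feats <- tiny_features()
  sub <- mercl:::features_subset(feats, seq_len(24))
  cfg <- tiny_config(pretrain_epochs = 1L,
                     weights = mercl_weights(0, 0, 1))
  enc <- pretrain(sub, cfg)
  ll <- tidy(enc)
  expect_true(all(is.finite(c(ll$amcl, ll$emcl, ll$smcl))))
  expect_equal(ll$total, ll$smcl, tolerance = 1e-12)
})

test_that("fine-tuning freezes encoder parameters unless unfrozen", {
  feats <- tiny_features()
  sub <- mercl:::features_subset(feats, seq_len(48))
  cfg <- tiny_config(pretrain_epochs = 1L, finetune_epochs = 2L)
  enc <- pretrain(sub, cfg)
  before <- mercl:::tree_sumsq(enc$params$tcn)
  model <- finetune(sub, enc, cfg)
  expect_identical(model$encoder$params$tcn, enc$params$tcn)
  expect_equal(mercl:::tree_sumsq(model$encoder$params$tcn), before)
  # cross-entropy decreases on the training split
  ll <- tidy(model)
  expect_lt(ll$cross_entropy[nrow(ll)], ll$cross_entropy[1])

  cfg_u <- tiny_config(pretrain_epochs = 1L, finetune_epochs = 2L,
                       freeze_encoders = FALSE)
  model_u <- finetune(sub, enc, cfg_u)
  expect_false(identical(model_u$encoder$params$tcn, enc$params$tcn))
})

test_that("near-noiseless separable data is fit perfectly within 50 epochs", {
  ds <- generate_synth_dataset(synth_spec(
    n_trials_per_class = 2L, trial_len_s = 4, audio_fs = 8000,
    latent_sd = 0.05, noise_sd = c(video = 0.01, audio = 0.001, eeg = 0.05),
    silent_audio_frac = 0, seed = 77L))
  feats <- prepare_blocks(ds)
  cfg <- tiny_config(pretrain_epochs = 2L, finetune_epochs = 50L)
  model <- finetune(feats, pretrain(feats, cfg), cfg)
  expect_equal(max(tidy(model)$train_accuracy), 1)
})

test_that("stratified trial-level cross-validation partitions and aggregates correctly", {
  ds <- tiny_dataset()   # 16 trials, 4 per class, 3 blocks each
  feats <- tiny_features()
  cfg <- tiny_config(pretrain_epochs = 1L, finetune_epochs = 3L)
  cv <- cross_validate(ds, cfg, k = 4L, features = feats)
  expect_s3_class(cv, "mercl_cv")
  # folds partition the trials, one trial per class per fold
  fm <- cv$fold_map
  expect_equal(sort(unique(fm$fold)), 1:4)
  expect_equal(unname(table(fm$fold)), rep(4L, 4), ignore_attr = TRUE)
  for (f in 1:4)
    expect_equal(sort(fm$label[fm$fold == f]), 0:3)
  # every trial evaluated exactly once as test
  expect_setequal(fm$trial, unique(feats$trial))
  # aggregation is the arithmetic mean over folds
  expect_equal(cv$mean_accuracy, mean(cv$folds$accuracy))
  expect_equal(cv$mean_f1, mean(cv$folds$f1_macro))
  expect_equal(sum(cv$folds$n_test), length(feats$labels))
  # deterministic fold map under the same seed
  cv2 <- cross_validate(ds, cfg, k = 4L, features = feats)
  expect_identical(cv2$fold_map, cv$fold_map)
  expect_equal(cv2$folds, cv$folds)
  # tidy/glance surfaces
  expect_identical(tidy(cv), cv$folds)
  expect_equal(glance(cv)$mean_accuracy, cv$mean_accuracy)
})

test_that("cross-validation refuses classes with fewer trials than folds", {
  ds <- tiny_dataset()
  feats <- tiny_features()
  keep <- feats$trial != unique(feats$trial)[1]  # class 0 loses one trial
  sub <- mercl:::features_subset(feats, which(keep))
  expect_error(cross_validate(ds, tiny_config(), k = 4L, features = sub),
               "at least")
})

test_that("balanced 40-trial data yields four disjoint balanced folds", {
  labels <- rep(0:3, each = 10)
  f <- mercl:::stratified_folds(labels, 4L, seed = 99L)
  expect_equal(unname(table(f)), rep(10L, 4), ignore_attr = TRUE)
  # stratification: folds get 2 or 3 trials of each class
  for (cl in 0:3)
    expect_true(all(table(f[labels == cl]) %in% 2:3))
  # determinism and permutation equivariance of the seeded assignment
  expect_identical(mercl:::stratified_folds(labels, 4L, 99L), f)
})

test_that("training appends JSON-lines diagnostics when a log file is set", {
  feats <- tiny_features()
  sub <- mercl:::features_subset(feats, seq_len(24))
  lf <- withr::local_tempfile(fileext = ".jsonl")
  cfg <- tiny_config(pretrain_epochs = 2L, finetune_epochs = 1L,
                     log_file = lf)
  model <- finetune(sub, pretrain(sub, cfg), cfg)
  lines <- readLines(lf)
  expect_length(lines, 3L)  # 2 pretrain + 1 finetune epochs
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$stage, "pretrain")
  expect_true(all(c("total", "amcl", "emcl", "smcl", "skipped_smcl") %in%
                    names(rec)))
  expect_equal(jsonlite::fromJSON(lines[3])$stage, "finetune")
})
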