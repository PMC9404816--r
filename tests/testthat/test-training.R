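test_that("kfold_split partitions 97 items into the 78/19 protocol folds", {
  splits <- kfold_split(97, train_config(k_folds = 5, split_seed = 3))
  val_sizes <- vapply(splits, function(s) length(s$val), integer(1))
  expect_setequal(val_sizes, c(19L, 20L))
  expect_equal(sum(val_sizes), 97L)
  # at least one fold realizes the 78-train / 19-validation split
  expect_true(any(vapply(splits, function(s)
    length(s$train) == 78 && length(s$val) == 19, logical(1))))
  # validation sets are pairwise disjoint and cover everything
  all_val <- unlist(lapply(splits, `[[`, "val"))
  expect_equal(sort(all_val), 1:97)
  for (s in splits) {
    expect_length(intersect(s$train, s$val), 0)
    expect_equal(sort(c(s$train, s$val)), 1:97)
  }
})

test_that("kfold_split handles exact divisions and rejects n < k", {
  splits <- kfold_split(10, train_config(k_folds = 5))
  expect_true(all(vapply(splits, function(s) length(s$val), integer(1)) == 2L))
  expect_equal(sort(unlist(lapply(splits, `[[`, "val"))), 1:10)
  expect_error(kfold_split(4, train_config(k_folds = 5)), "cannot split")
  # deterministic under the seed, different across seeds
  a <- kfold_split(20, train_config(split_seed = 9))
  b <- kfold_split(20, train_config(split_seed = 9))
  expect_identical(a, b)
  c <- kfold_split(20, train_config(split_seed = 10))
  expect_false(identical(a, c))
})

test_that("BCE hits its closed forms and matches a scalar-loop oracle", {
  y <- list(random_mask(8, 8, 0.5))
  half <- list(matrix(0.5, 8, 8))
  expect_equal(bce_loss(half, y), log(2), tolerance = 1e-9)
  # perfect prediction, clipped at 1e-7
  exact <- list(y[[1]] * 1.0)
  expect_lte(bce_loss(exact, y), 1.2e-6)
  # random case against an explicit per-pixel summation
  set.seed(88)
  preds <- lapply(1:4, function(i) matrix(runif(64, 0.01, 0.99), 8, 8))
  ys <- lapply(1:4, function(i) random_mask(8, 8, 0.4))
  acc <- 0
  for (o in 1:4) {
    s <- 0
    for (px in 1:64) {
      p <- preds[[o]][px]; yy <- ys[[o]][px]
      s <- s - (yy * log(p) + (1 - yy) * log(1 - p))
    }
    acc <- acc + s / 64
  }
  expect_equal(bce_loss(preds, ys), acc / 4, tolerance = 1e-10)
  expect_error(bce_loss(preds, ys[1:2]), "number of outputs")
  expect_error(bce_loss(list(matrix(0.5, 4, 4)), list(random_mask(8, 8))), "shape")
})

test_that("train_fold records bookkeeping and a zero learning rate freezes weights", {
  samples <- tiny_samples(6)
  cfg <- tiny_model_config()
  m <- build_model(cfg, init_seed = 1)
  tc0 <- train_config(epochs = 2, batch_size = 2, learning_rate = 0, augment = FALSE)
  r0 <- train_fold(m, samples[1:4], tc0, val_samples = samples[5:6])
  expect_length(r0$loss_history, 2)
  expect_true(all(r0$loss_history >= 0))
  expect_identical(r0$model$params, m$params)       # null update
  expect_equal(nrow(r0$records), 2 * 4)             # images x outputs
  expect_error(train_fold(m, list(), tc0), "empty")

  tc <- train_config(epochs = 2, batch_size = 2, learning_rate = 5e-4,
                     augment = FALSE)
  r <- train_fold(m, samples[1:4], tc)
  expect_false(identical(r$model$params, m$params))
})

test_that("training is deterministic under fixed seeds", {
  samples <- tiny_samples(4)
  m <- build_model(tiny_model_config(), init_seed = 2)
  tc <- train_config(epochs = 1, batch_size = 2, shuffle_seed = 5, augment = FALSE)
  r1 <- train_fold(m, samples, tc)
  r2 <- train_fold(m, samples, tc)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$loss_history, r2$loss_history)
})

test_that("cross_validate shares one initialization and persists per-fold weights", {
  samples <- tiny_samples(5)
  mcfg <- tiny_model_config()
  tcfg <- train_config(k_folds = 5, epochs = 1, batch_size = 2,
                       learning_rate = 0, augment = FALSE)
  out_dir <- withr::local_tempdir()
  res <- cross_validate(samples, mcfg, tcfg, out_dir = out_dir)
  expect_length(res$folds, 5)
  expect_true(file.exists(res$init_weights_path))
  wfiles <- list.files(out_dir, pattern = "^fold_\\d_weights\\.rds$")
  expect_length(wfiles, 5)                          # five sets of weights
  # lr = 0: every fold's final weights equal the shared initialization
  init <- readRDS(res$init_weights_path)
  for (f in res$folds) expect_identical(f$model$params, init)
  # summary table aggregates all five folds
  expect_s3_class(res$table, "metrics_table")
  expect_equal(nrow(attr(res$table, "fold_means")), 5)
  expect_true(all(res$table$sd >= 0))
  expect_true(file.exists(file.path(out_dir, "summary.csv")))
  expect_true(file.exists(file.path(out_dir, "train.log")))
})

test_that("fold assignments are identical across repeated cross-validation runs", {
  s1 <- kfold_split(12, train_config(k_folds = 3, split_seed = 42))
  s2 <- kfold_split(12, train_config(k_folds = 3, split_seed = 42))
  expect_identical(s1, s2)
})

test_that("training on augmented folds consumes the 4x expansion", {
  samples <- tiny_samples(2)
  aug <- augment_fold(samples, augment_params(rng_seed = 3))
  m <- build_model(tiny_model_config(), init_seed = 4)
  tc <- train_config(epochs = 1, batch_size = 4, augment = FALSE)
  r <- train_fold(m, aug, tc)
  expect_length(r$loss_history, 1)
  expect_true(is.finite(r$loss_history))
})
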