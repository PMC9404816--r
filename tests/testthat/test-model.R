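test_that("configuration invariants are enforced", {
  expect_error(model_config(input_size = 100, depth = 5), "divisible")
  expect_error(model_config(dropout_rate = 1), "dropout_rate")
  expect_error(model_config(threshold = 0), "threshold")
  expect_error(model_config(kernel_size = 4), "kernel_size")
})

test_that("default architecture maps 3x256x256 to four 1x256x256 sigmoid outputs", {
  # shapes are verified on the real default layer schedule (no forward pass
  # at 256 needed): sides halve per level, channels follow 16/32/64/128/256
  cfg <- model_config()
  tab <- summary(build_model(cfg))
  enc <- tab[grepl("^enc", tab$layer), ]
  expect_equal(enc$channels, rep(c(16, 32, 64, 128, 256), each = 2))
  expect_equal(enc$side, rep(c(256, 128, 64, 32, 16), each = 2))
  expect_equal(max(tab$channels[grepl("^enc5", tab$layer)]), 256)  # bottleneck width
  # four decoders, each ending in a single-channel 256 x 256 output
  outs <- tab[grepl("^out", tab$layer), ]
  expect_equal(nrow(outs), 4)
  expect_equal(outs$channels, rep(1, 4))
  expect_equal(outs$side, rep(256, 4))
})

test_that("a forward pass yields probability maps of the input size in [0,1]", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, init_seed = 2)
  s <- tiny_samples(1)[[1]]
  seg <- predict(m, s$image)
  expect_s3_class(seg, "segmentation_result")
  expect_equal(seg$combo_order, COMBOS)
  for (cmb in COMBOS) {
    expect_equal(dim(seg$prob_maps[[cmb]]), c(16, 16))
    expect_true(all(seg$prob_maps[[cmb]] >= 0 & seg$prob_maps[[cmb]] <= 1))
    expect_true(all(seg$binary_masks[[cmb]] %in% c(0L, 1L)))
  }
})

test_that("parameter count matches the closed-form layer-schedule sum", {
  # independent oracle: k^2 * c_in * c_out + c_out summed over the schedule
  count_oracle <- function(bf, depth, k, n_out, cin0) {
    f <- function(L) bf * 2^(L - 1)
    total <- 0
    cin <- cin0
    for (L in seq_len(depth)) {
      total <- total + k^2 * cin * f(L) + f(L) + k^2 * f(L)^2 + f(L)
      cin <- f(L)
    }
    dec <- 0
    prev <- f(depth)
    for (L in rev(seq_len(depth - 1))) {
      dec <- dec + k^2 * (prev + f(L)) * f(L) + f(L) + k^2 * f(L)^2 + f(L)
      prev <- f(L)
    }
    dec <- dec + 1 * bf * 1 + 1          # final 1x1 conv
    total + n_out * dec
  }
  cfg <- model_config()                   # the default 256 x 256 network
  expect_equal(count_parameters(build_model(cfg)),
               count_oracle(16, 5, 5, 4, 3))
  cfg2 <- tiny_model_config()
  expect_equal(count_parameters(build_model(cfg2)),
               count_oracle(4, 3, 3, 4, 3))
})

test_that("decoder parameters scale as param(4) - param(1) = 3 x decoder share", {
  base <- list(input_size = 32, depth = 3, base_filters = 4, kernel_size = 3)
  p4 <- count_parameters(build_model(do.call(model_config, c(base, n_outputs = 4))))
  p1 <- count_parameters(build_model(do.call(model_config, c(base, n_outputs = 1))))
  p2 <- count_parameters(build_model(do.call(model_config, c(base, n_outputs = 2))))
  dec1 <- p2 - p1                         # one decoder's parameters
  expect_equal(p4 - p1, 3 * dec1)
  # monotonicity in width
  pw <- count_parameters(build_model(do.call(model_config, c(
    list(input_size = 32, depth = 3, base_filters = 8, kernel_size = 3), n_outputs = 4))))
  expect_gt(pw, p4)
})

test_that("single-decoder configuration reproduces the classical U-Net shapes", {
  cfg <- model_config(input_size = 64, n_outputs = 1, depth = 4, base_filters = 16)
  tab <- summary(build_model(cfg))
  # hand-enumerated: encoder 64/32/16/8 sides, decoder back to 64, one output
  expect_equal(tab$side[grepl("^enc", tab$layer)], rep(c(64, 32, 16, 8), each = 2))
  expect_equal(tab$side[grepl("^dec1", tab$layer)], rep(c(16, 32, 64), each = 2))
  expect_equal(sum(grepl("^out", tab$layer)), 1)
})

test_that("perturbing one decoder changes only its own output", {
  cfg <- tiny_model_config(dropout_rate = 0)
  m <- build_model(cfg, init_seed = 5)
  s <- tiny_samples(1)[[1]]
  base <- predict(m, s$image)
  m2 <- m
  m2$params$dec2_l1_c2_W <- m2$params$dec2_l1_c2_W +
    matrix(0.5, nrow(m2$params$dec2_l1_c2_W), ncol(m2$params$dec2_l1_c2_W))
  pert <- predict(m2, s$image)
  expect_identical(base$prob_maps$RG, pert$prob_maps$RG)
  expect_identical(base$prob_maps$GB, pert$prob_maps$GB)
  expect_identical(base$prob_maps$RGB, pert$prob_maps$RGB)
  expect_false(identical(base$prob_maps$RB, pert$prob_maps$RB))
})

test_that("encoder perturbation changes every output", {
  cfg <- tiny_model_config(dropout_rate = 0)
  m <- build_model(cfg, init_seed = 5)
  s <- tiny_samples(1)[[1]]
  base <- predict(m, s$image)
  m$params$enc1_c1_W <- m$params$enc1_c1_W * 1.5
  pert <- predict(m, s$image)
  for (cmb in COMBOS) {
    expect_false(identical(base$prob_maps[[cmb]], pert$prob_maps[[cmb]]), label = cmb)
  }
})

test_that("binarization uses strict > and is idempotent", {
  half <- matrix(0.5, 4, 4)
  expect_equal(binarize(half, 0.5), matrix(0L, 4, 4))
  x <- matrix(runif(64), 8, 8)
  b1 <- binarize(x, 0.5)
  expect_identical(binarize(b1, 0.5), b1)
  expect_identical(binarize(binarize(x, 0.3), 0.3), binarize(x, 0.3))
})

test_that("shape mismatches in predict name expected and received shapes", {
  m <- build_model(tiny_model_config())
  bad <- array(0.5, c(8, 8, 3))
  expect_error(predict(m, bad), "16 x 16 x 3.*8 x 8 x 3")
})

test_that("weight initialization is reproducible and persistable", {
  cfg <- tiny_model_config()
  m1 <- build_model(cfg, init_seed = 11)
  m2 <- build_model(cfg, init_seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, init_seed = 12)
  expect_false(identical(m1$params, m3$params))

  path <- withr::local_tempfile(fileext = ".rds")
  save_weights(m1, path)
  restored <- load_weights(m3, path)
  expect_identical(restored$params, m1$params)
  # mismatched layouts are refused
  other <- build_model(model_config(input_size = 16, depth = 2, base_filters = 2,
                                    kernel_size = 3))
  expect_error(load_weights(other, path), "layout")
})

test_that("the fixed-limit uniform initializer option draws in [-1, 1]", {
  cfg <- tiny_model_config(init_scheme = "uniform_pm1")
  m <- build_model(cfg, init_seed = 1)
  w <- unlist(m$params[grepl("_W$", names(m$params))])
  expect_true(all(abs(w) <= 1))
  expect_gt(max(abs(w)), 0.9)             # actually uses the full interval
  # glorot draws respect the fan-based limit layer by layer
  g <- build_model(tiny_model_config(), init_seed = 1)
  expect_lt(max(abs(g$params$enc1_c1_W)), sqrt(6 / (9 * 3 + 9 * 4)))
  expect_lt(max(abs(g$params$enc2_c2_W)), sqrt(6 / (9 * 8 + 9 * 8)))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- model_config(input_size = 8, input_channels = 2, n_outputs = 2,
                      depth = 2, base_filters = 3, kernel_size = 3,
                      dropout_rate = 0)
  m <- build_model(cfg, init_seed = 7)
  set.seed(1)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  y <- list(matrix(rbinom(64, 1, 0.4), 8, 8), matrix(rbinom(64, 1, 0.4), 8, 8))
  loss_fn <- function(mm) bce_loss(tangleseg:::nn_forward(mm, x)$probs, y)
  fw <- tangleseg:::nn_forward(m, x)
  dlogits <- lapply(1:2, function(o) (fw$probs[[o]] - y[[o]]) / (64 * 2))
  gr <- tangleseg:::nn_backward(m, fw$cache, dlogits)
  hstep <- 1e-6
  for (nm in c("enc1_c1_W", "enc2_c2_W", "dec1_l1_c1_W", "dec2_l1_c2_W",
               "out1_W", "enc1_c2_b", "out2_b")) {
    for (rep in 1:3) {
      i <- sample(length(m$params[[nm]]), 1)
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + hstep
      mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - hstep
      num <- (loss_fn(mp) - loss_fn(mn)) / (2 * hstep)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-3,
                   label = sprintf("d(loss)/d(%s[%d])", nm, i))
    }
  }
})
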