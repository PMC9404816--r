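test_that("right-angle rotations obey the group laws", {
  s <- tiny_samples(1)[[1]]
  r <- s
  for (i in 1:4) r <- rotate_sample(r$image, r$masks, 90)
  expect_equal(unclass(r$image), unclass(s$image), ignore_attr = TRUE)
  expect_identical(r$masks, s$masks)
  r2 <- rotate_sample(s$image, s$masks, 180)
  r2 <- rotate_sample(r2$image, r2$masks, 180)
  expect_equal(unclass(r2$image), unclass(s$image), ignore_attr = TRUE)
  # 90 then 270 is also the identity
  r3 <- rotate_sample(s$image, s$masks, 90)
  r3 <- rotate_sample(r3$image, r3$masks, 270)
  expect_equal(unclass(r3$image), unclass(s$image), ignore_attr = TRUE)
  expect_error(rotate_sample(s$image, s$masks, 45), "90, 180")
})

test_that("90-degree rotation matches the index-permutation oracle on a labeled grid", {
  S <- 4
  m <- matrix(seq_len(S * S), S, S)          # every pixel uniquely labeled
  rot <- tangleseg:::rot_matrix(m, 90)
  # counterclockwise: 0-based (r, c) lands at (S-1-c, r)
  for (r0 in 0:(S - 1)) {
    for (c0 in 0:(S - 1)) {
      expect_equal(rot[S - c0, r0 + 1], m[r0 + 1, c0 + 1])
    }
  }
  rot270 <- tangleseg:::rot_matrix(m, 270)   # inverse permutation
  for (r0 in 0:(S - 1)) {
    for (c0 in 0:(S - 1)) {
      expect_equal(rot270[c0 + 1, S - r0], m[r0 + 1, c0 + 1])
    }
  }
})

test_that("zero-amplitude elastic deformation is the identity", {
  s <- tiny_samples(1)[[1]]
  ap <- augment_params(elastic_alpha = 0, elastic_sigma = 4, rng_seed = 3)
  d <- elastic_deform_sample(s$image, s$masks, ap, seed = 1)
  expect_equal(unclass(d$image), unclass(s$image), ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(d$masks, s$masks)
})

test_that("deformed masks stay binary and registered with the image", {
  s <- tiny_samples(1, size = 32)[[1]]
  ap <- augment_params(elastic_alpha = 10, elastic_sigma = 3, rng_seed = 5)
  d <- elastic_deform_sample(s$image, s$masks, ap, seed = 9)
  for (cmb in COMBOS) expect_true(all(d$masks[[cmb]] %in% c(0L, 1L)))
  expect_equal(dim(unclass(d$image)), dim(unclass(s$image)))
  # same seed, same field: deterministic
  d2 <- elastic_deform_sample(s$image, s$masks, ap, seed = 9)
  expect_identical(unclass(d$image), unclass(d2$image))
  expect_identical(d$masks, d2$masks)
})

test_that("the displacement field equals a direct smooth-then-scale convolution oracle", {
  ap <- augment_params(elastic_alpha = 34, elastic_sigma = 4, rng_seed = 2)
  shape <- c(48, 48)
  fld <- withr::with_seed(123, elastic_field(shape, ap))
  # oracle: same uniform draws, direct edge-replicated convolution
  sig <- 4; rad <- ceiling(4 * sig)
  g <- dnorm(seq(-rad, rad), sd = sig); kern <- outer(g, g); kern <- kern / sum(kern)
  oracle <- withr::with_seed(123, {
    ur <- matrix(runif(prod(shape), -1, 1), shape[1], shape[2])
    uc <- matrix(runif(prod(shape), -1, 1), shape[1], shape[2])
    list(dr = 34 * tangleseg:::.conv2_replicate(ur, kern),
         dc = 34 * tangleseg:::.conv2_replicate(uc, kern))
  })
  expect_equal(fld$dr, oracle$dr, tolerance = 1e-8)
  expect_equal(fld$dc, oracle$dc, tolerance = 1e-8)
  # field magnitude is bounded by alpha (kernel is an average of [-1,1] draws)
  expect_true(max(abs(c(fld$dr, fld$dc))) <= 34)
})

test_that("augment_fold quadruples the fold with provenance", {
  fold <- tiny_samples(3)
  ap <- augment_params(rng_seed = 4)
  out <- augment_fold(fold, ap)
  expect_length(out, 12)
  expect_equal(vapply(out, `[[`, numeric(1), "source_index"), rep(1:3, each = 4))
  chains <- vapply(out[1:4], `[[`, character(1), "transforms")
  expect_equal(chains[1], "identity")
  expect_match(chains[2], "^rot(90|180|270)$")
  expect_equal(chains[3], "elastic")
  expect_match(chains[4], "^rot(90|180|270)\\+elastic$")
  for (o in out) {
    expect_equal(dim(unclass(o$image)), dim(unclass(fold[[1]]$image)))
  }
  # single-sample fold gives 4 distinct transform chains
  out1 <- augment_fold(fold[1], ap)
  expect_length(out1, 4)
  expect_length(unique(vapply(out1, `[[`, character(1), "transforms")), 4)
  expect_error(augment_fold(list(), ap), "non-empty")
})

test_that("rotation registration is exact: mask(rotated) = rotate(mask)", {
  s <- tiny_samples(1)[[1]]
  r <- rotate_sample(s$image, s$masks, 270)
  for (cmb in COMBOS) {
    expect_identical(r$masks[[cmb]], tangleseg:::rot_matrix(s$masks[[cmb]], 270))
  }
})

test_that("augmentation is deterministic under a fixed seed", {
  fold <- tiny_samples(2)
  a <- augment_fold(fold, augment_params(rng_seed = 77))
  b <- augment_fold(fold, augment_params(rng_seed = 77))
  for (i in seq_along(a)) {
    expect_identical(unclass(a[[i]]$image), unclass(b[[i]]$image))
    expect_identical(a[[i]]$masks, b[[i]]$masks)
  }
})

test_that("augmented datasets persist with a transform-chain column", {
  dir <- withr::local_tempdir()
  sp <- tiny_synth(size = 24, seed = 3)
  generate_dataset(sp, 2, dir)
  out <- file.path(dir, "aug")
  man <- augment_dataset(file.path(dir, "manifest.csv"), out,
                         augment_params(rng_seed = 1))
  expect_equal(nrow(man), 8)
  expect_true("transforms" %in% names(man))
  expect_true(all(file.exists(man$image_path)))
})
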