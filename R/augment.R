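#' Augmentation parameters
#'
#' Training-set expansion: one right-angle rotation drawn uniformly per
#' sample, plus one random elastic deformation of the original and one of
#' the rotated sample, quadrupling the fold.  The elastic displacement field
#' is a per-pixel uniform field in `[-1, 1]^2`, Gaussian-smoothed with
#' `elastic_sigma` and scaled by `elastic_alpha` (the classic alpha = 34,
#' sigma = 4 defaults of the elastic-deformation literature).
#'
#' @param rotation_angles allowed rotation angles, a subset of
#'   `c(90, 180, 270)` degrees (counterclockwise).
#' @param elastic_alpha displacement magnitude in pixels (>= 0).
#' @param elastic_sigma Gaussian smoothing scale of the displacement field
#'   in pixels (> 0).
#' @param rng_seed integer seed for angle and field draws.
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(rotation_angles = c(90, 180, 270),
                           elastic_alpha = 34, elastic_sigma = 4,
                           rng_seed = 1L) {
  if (length(rotation_angles) < 1 || !all(rotation_angles %in% c(90, 180, 270))) {
    stop_config("rotation_angles", "must be a non-empty subset of {90, 180, 270}")
  }
  if (elastic_alpha < 0) stop_config("elastic_alpha", "must be >= 0")
  if (elastic_sigma <= 0) stop_config("elastic_sigma", "must be > 0")
  structure(list(
    rotation_angles = as.numeric(rotation_angles),
    elastic_alpha = as.numeric(elastic_alpha),
    elastic_sigma = as.numeric(elastic_sigma),
    rng_seed = as.integer(rng_seed)
  ), class = "augment_params")
}

# exact (lossless) counterclockwise right-angle rotation of a matrix
rot_matrix <- function(m, angle) {
  n <- nrow(m)
  switch(as.character(angle),
         "90"  = t(m[, rev(seq_len(ncol(m))), drop = FALSE]),
         "180" = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
         "270" = t(m)[, rev(seq_len(n)), drop = FALSE],
         stop("rot_matrix: angle must be 90, 180 or 270", call. = FALSE))
}

#' Rotate an image and its masks by a right angle
#'
#' Rotation is a pure index permutation (counterclockwise), so it is
#' lossless: no interpolation, masks stay binary, and image-mask
#' registration is exact.
#'
#' @param image a [fluorescence_image].
#' @param masks a [mask_set].
#' @param angle one of 90, 180, 270 (degrees counterclockwise).
#' @return A list with rotated `image` and `masks`.
#' @export
rotate_sample <- function(image, masks, angle) {
  if (length(angle) != 1 || !angle %in% c(90, 180, 270)) {
    stop("rotate_sample: angle must be one of 90, 180, 270", call. = FALSE)
  }
  arr <- unclass(image)
  rot <- array(0, dim(arr)[c(2, 1, 3)])
  for (ch in seq_len(dim(arr)[3])) rot[, , ch] <- rot_matrix(arr[, , ch], angle)
  list(image = fluorescence_image(rot, meta = attr(image, "meta")),
       masks = mask_set(lapply(masks, rot_matrix, angle = angle)))
}

#' Sample a smoothed elastic displacement field
#'
#' Draws an independent uniform field in `[-1, 1]` per pixel for each of the
#' row and column displacement components, smooths each with a Gaussian
#' kernel (sd `elastic_sigma`, truncated at 4 sigma, edge-replicated
#' borders) and scales by `elastic_alpha`.  Exposed separately so the field
#' can be inspected and tested against a direct-convolution computation.
#'
#' @param shape length-2 integer, the raster dimension (rows, cols).
#' @param params an [augment_params].
#' @return A list with matrices `dr` (row displacement) and `dc` (column
#'   displacement), in pixels.
#' @export
elastic_field <- function(shape, params) {
  stopifnot(inherits(params, "augment_params"))
  sig <- params$elastic_sigma
  r <- ceiling(4 * sig)
  g <- dnorm(seq(-r, r), sd = sig)
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  smooth <- function(u) {
    if (nrow(u) <= 2 * r || ncol(u) <= 2 * r) {
      # raster smaller than the kernel: fall back to explicit padding + direct conv
      return(.conv2_replicate(u, kern))
    }
    EBImage::filter2(u, kern, boundary = "replicate")
  }
  ur <- matrix(runif(prod(shape), -1, 1), shape[1], shape[2])
  uc <- matrix(runif(prod(shape), -1, 1), shape[1], shape[2])
  list(dr = params$elastic_alpha * smooth(ur),
       dc = params$elastic_alpha * smooth(uc))
}

# direct 2-D correlation with replicated edges (small rasters / oracle path)
.conv2_replicate <- function(u, kern) {
  r <- (nrow(kern) - 1) / 2
  H <- nrow(u); W <- ncol(u)
  idx_r <- pmin(pmax(seq(1 - r, H + r), 1), H)
  idx_c <- pmin(pmax(seq(1 - r, W + r), 1), W)
  P <- u[idx_r, idx_c, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      out <- out + kern[i, j] * P[(i - 1) + seq_len(H), (j - 1) + seq_len(W)]
    }
  }
  out
}

# Resample `m` at source positions (i + dr, j + dc); bilinear or nearest,
# with edge replication (coordinates clamped to the raster).
warp_matrix <- function(m, dr, dc, bilinear = TRUE) {
  H <- nrow(m); W <- ncol(m)
  sr <- pmin(pmax(matrix(seq_len(H), H, W) + dr, 1), H)
  sc <- pmin(pmax(matrix(seq_len(W), H, W, byrow = TRUE) + dc, 1), W)
  if (!bilinear) {
    return(matrix(m[cbind(as.vector(round(sr)), as.vector(round(sc)))], H, W))
  }
  r0 <- pmin(floor(sr), H - 1); c0 <- pmin(floor(sc), W - 1)
  fr <- sr - r0; fc <- sc - c0
  g <- function(ri, ci) matrix(m[cbind(as.vector(ri), as.vector(ci))], H, W)
  (1 - fr) * (1 - fc) * g(r0, c0) + fr * (1 - fc) * g(r0 + 1, c0) +
    (1 - fr) * fc * g(r0, c0 + 1) + fr * fc * g(r0 + 1, c0 + 1)
}

#' Elastically deform an image and its masks with one shared field
#'
#' One displacement field is sampled and applied identically to the image
#' (bilinear resampling) and to every mask (nearest-neighbour resampling,
#' then re-binarized), preserving image-mask registration.  Out-of-border
#' lookups replicate the edge pixel.
#'
#' @param image a [fluorescence_image].
#' @param masks a [mask_set].
#' @param params an [augment_params].
#' @param seed optional integer; when given, the field is drawn under this
#'   seed (otherwise from the current RNG stream).
#' @return A list with deformed `image` and `masks`.
#' @export
elastic_deform_sample <- function(image, masks, params, seed = NULL) {
  stopifnot(inherits(params, "augment_params"))
  arr <- unclass(image)
  fld <- if (is.null(seed)) {
    elastic_field(dim(arr)[1:2], params)
  } else {
    with_seed(seed, elastic_field(dim(arr)[1:2], params))
  }
  out <- arr
  for (ch in seq_len(dim(arr)[3])) {
    out[, , ch] <- warp_matrix(arr[, , ch], fld$dr, fld$dc, bilinear = TRUE)
  }
  out <- pmin(pmax(out, 0), 1)
  new_masks <- lapply(masks, function(m) {
    binarize(warp_matrix(m, fld$dr, fld$dc, bilinear = FALSE), 0.5)
  })
  list(image = fluorescence_image(out, meta = attr(image, "meta")),
       masks = mask_set(new_masks))
}

#' Expand a training fold fourfold
#'
#' For each sample: keep the original; add a copy rotated by one angle drawn
#' uniformly from `rotation_angles`; add an elastic deformation of the
#' original; add an elastic deformation of the rotated copy (independent
#' field).  A fold of 78 samples therefore yields 312 training samples.
#' Each output carries provenance: the source index and its transform chain.
#'
#' @param fold non-empty list of samples, each `list(image, masks)`.
#' @param params an [augment_params]; all draws derive from its `rng_seed`.
#' @return A list of `4 * length(fold)` samples, each with `image`, `masks`,
#'   `source_index` and `transforms` (character vector).
#' @export
augment_fold <- function(fold, params = augment_params()) {
  stopifnot(inherits(params, "augment_params"))
  if (length(fold) == 0) stop("augment_fold: fold must be non-empty", call. = FALSE)
  with_seed(derive_seed(params$rng_seed, 1L), {
    out <- vector("list", 4L * length(fold))
    j <- 0L
    for (i in seq_along(fold)) {
      s <- fold[[i]]
      angle <- params$rotation_angles[sample.int(length(params$rotation_angles), 1L)]
      rot <- rotate_sample(s$image, s$masks, angle)
      el1 <- elastic_deform_sample(s$image, s$masks, params)
      el2 <- elastic_deform_sample(rot$image, rot$masks, params)
      chains <- list(
        list(s = s, tr = "identity"),
        list(s = rot, tr = sprintf("rot%d", angle)),
        list(s = el1, tr = "elastic"),
        list(s = el2, tr = sprintf("rot%d+elastic", angle))
      )
      for (ch in chains) {
        j <- j + 1L
        out[[j]] <- list(image = ch$s$image, masks = ch$s$masks,
                         source_index = i, transforms = ch$tr)
      }
    }
    out
  })
}

#' Augment a persisted dataset
#'
#' Reads a manifest, expands every sample with [augment_fold()] and writes
#' the augmented samples in the same PNG + manifest layout, with an
#' additional `transforms` provenance column.
#'
#' @param manifest_path path to the source `manifest.csv`.
#' @param out_dir output directory.
#' @param params an [augment_params].
#' @return The augmented manifest data frame, invisibly.
#' @export
augment_dataset <- function(manifest_path, out_dir, params = augment_params()) {
  samples <- read_dataset(manifest_path)
  aug <- augment_fold(samples, params)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("augment_dataset: cannot create '%s'", out_dir), call. = FALSE)
  rows <- vector("list", length(aug))
  for (i in seq_along(aug)) {
    img_path <- file.path(out_dir, sprintf("aug_%04d.png", i))
    write_image(aug[[i]]$image, img_path)
    mask_paths <- vapply(COMBOS, function(cmb) {
      p <- file.path(out_dir, sprintf("aug_%04d_%s.png", i, cmb))
      write_mask(aug[[i]]$masks[[cmb]], p)
      p
    }, character(1))
    rows[[i]] <- data.frame(
      image_path = img_path,
      mask_RG = mask_paths["RG"], mask_RB = mask_paths["RB"],
      mask_GB = mask_paths["GB"], mask_RGB = mask_paths["RGB"],
      seed = params$rng_seed, index = i,
      source_index = aug[[i]]$source_index, transforms = aug[[i]]$transforms
    )
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
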