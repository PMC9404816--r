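#' Parameters of the synthetic fluorescence image generator
#'
#' The generator emulates triple-label immunofluorescence acquisitions of
#' neurofibrillary tangles: bright blob-like "tangle cores" whose per-channel
#' footprints overlap partially, on a noisy low-intensity background.  Each
#' core is an isotropic 2-D Gaussian intensity profile, present in each
#' colour channel independently with the given probability and with a
#' per-channel peak drawn from `core_intensity_range`.  Ground truth for a
#' channel combination is the set of pixels showing significant intensity
#' (above `intensity_threshold`) in every channel of the combination, inside
#' some core footprint.
#'
#' @param image_size pixels per side (square images).
#' @param n_cores number of tangle cores per image (may be 0).
#' @param core_radius_range length-2 numeric, min/max core footprint radius
#'   in pixels; the Gaussian profile sigma is half the radius, so the
#'   above-threshold disc lies inside the footprint.
#' @param channel_presence_probs length-3 probabilities that a core is
#'   bright in the R, G, B channel respectively.
#' @param core_intensity_range length-2 numeric in `[0, 1]`, the range of
#'   per-channel peak intensities.
#' @param background_noise_sigma sd of the additive Gaussian background
#'   noise (image is clipped to `[0, 1]` afterwards).
#' @param intensity_threshold the "significant intensity" cutoff in (0, 1)
#'   defining ground truth, as a fraction of the dynamic range.
#' @param rng_seed integer seed; identical seed and parameters give a
#'   bit-identical dataset.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(image_size = 256L,
                             n_cores = 6L,
                             core_radius_range = c(8, 20),
                             channel_presence_probs = c(0.9, 0.9, 0.9),
                             core_intensity_range = c(0.7, 1.0),
                             background_noise_sigma = 0.05,
                             intensity_threshold = 0.5,
                             rng_seed = 1L) {
  if (!is.numeric(image_size) || length(image_size) != 1L || image_size < 4) {
    stop_config("image_size", "must be a single integer >= 4")
  }
  if (!is.numeric(n_cores) || length(n_cores) != 1L || n_cores < 0) {
    stop_config("n_cores", "must be a single non-negative integer")
  }
  if (length(core_radius_range) != 2L || core_radius_range[1] < 1 ||
      core_radius_range[1] > core_radius_range[2]) {
    stop_config("core_radius_range", "must satisfy 1 <= min <= max")
  }
  if (length(channel_presence_probs) != 3L ||
      any(channel_presence_probs < 0) || any(channel_presence_probs > 1)) {
    stop_config("channel_presence_probs", "must be three probabilities in [0, 1]")
  }
  if (length(core_intensity_range) != 2L || core_intensity_range[1] < 0 ||
      core_intensity_range[2] > 1 ||
      core_intensity_range[1] > core_intensity_range[2]) {
    stop_config("core_intensity_range", "must be an increasing range within [0, 1]")
  }
  if (background_noise_sigma < 0) {
    stop_config("background_noise_sigma", "must be >= 0")
  }
  if (intensity_threshold <= 0 || intensity_threshold >= 1) {
    stop_config("intensity_threshold", "must lie in (0, 1)")
  }
  structure(list(
    image_size = as.integer(image_size),
    n_cores = as.integer(n_cores),
    core_radius_range = as.numeric(core_radius_range),
    channel_presence_probs = as.numeric(channel_presence_probs),
    core_intensity_range = as.numeric(core_intensity_range),
    background_noise_sigma = as.numeric(background_noise_sigma),
    intensity_threshold = as.numeric(intensity_threshold),
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_params")
}

#' Generate one synthetic sample (image + four ground-truth masks)
#'
#' Draws `n_cores` tangle cores (uniform centre, uniform radius, independent
#' per-channel presence and peak), renders each channel as the pixelwise
#' maximum of its core profiles, adds clipped Gaussian background noise, and
#' quantizes intensities to the 8-bit grid so that the in-memory image is
#' identical to its PNG round-trip.  Masks are then computed from the stored
#' image: pixel in mask(C) iff every channel of C exceeds the intensity
#' threshold and the pixel lies inside some core footprint.  By construction
#' mask(RGB) is nested inside each pairwise mask.
#'
#' @param params a [synthetic_params] object.
#' @param index sample index (>= 1); together with `rng_seed` it determines
#'   the sample, so samples are reproducible individually.
#' @return A list with elements `image` ([fluorescence_image]), `masks`
#'   ([mask_set]), and `cores` (data frame of core centre/radius/presence,
#'   useful for brute-force mask recomputation).
#' @export
generate_sample <- function(params, index = 1L) {
  stopifnot(inherits(params, "synthetic_params"))
  S <- params$image_size
  with_seed(derive_seed(params$rng_seed, index), {
    n <- params$n_cores
    cores <- data.frame(
      cy = runif(n, 1, S), cx = runif(n, 1, S),
      radius = runif(n, params$core_radius_range[1], params$core_radius_range[2])
    )
    pres <- matrix(runif(3 * n) < rep(params$channel_presence_probs, each = n),
                   nrow = n, ncol = 3)
    peak <- matrix(runif(3 * n, params$core_intensity_range[1],
                         params$core_intensity_range[2]), nrow = n, ncol = 3)
    colnames(pres) <- paste0("in_", c("R", "G", "B"))
    colnames(peak) <- paste0("peak_", c("R", "G", "B"))
    cores <- cbind(cores, pres, peak)

    img <- array(0, dim = c(S, S, 3))
    footprint <- matrix(FALSE, S, S)
    rr <- matrix(seq_len(S), S, S)
    cc <- matrix(seq_len(S), S, S, byrow = TRUE)
    for (i in seq_len(n)) {
      d2 <- (rr - cores$cy[i])^2 + (cc - cores$cx[i])^2
      footprint <- footprint | (d2 <= cores$radius[i]^2)
      prof <- exp(-d2 / (2 * (cores$radius[i] / 2)^2))
      for (ch in 1:3) {
        if (pres[i, ch]) img[, , ch] <- pmax(img[, , ch], peak[i, ch] * prof)
      }
    }
    if (params$background_noise_sigma > 0) {
      img <- img + rnorm(length(img), 0, params$background_noise_sigma)
    }
    img <- round(pmin(pmax(img, 0), 1) * 255) / 255

    masks <- lapply(.combo_channels, function(chs) {
      m <- footprint
      for (ch in chs) m <- m & (img[, , ch] > params$intensity_threshold)
      m * 1L
    })
    list(
      image = fluorescence_image(img, meta = list(index = index)),
      masks = mask_set(masks),
      cores = cores
    )
  })
}

#' Generate and persist a synthetic dataset
#'
#' Writes `n_images` samples to `dir` as 8-bit RGB PNG images and four
#' single-channel 8-bit PNG masks (values 0/255) each, plus `manifest.csv`
#' (columns `image_path, mask_RG, mask_RB, mask_GB, mask_RGB, seed, index`)
#' and the generating parameters as `params.yaml`.
#'
#' @param params a [synthetic_params] object.
#' @param n_images number of samples (>= 1).
#' @param dir output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
generate_dataset <- function(params, n_images, dir) {
  stopifnot(inherits(params, "synthetic_params"))
  if (!is.numeric(n_images) || n_images < 1) {
    stop("generate_dataset: n_images must be >= 1", call. = FALSE)
  }
  n_images <- as.integer(n_images)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop(sprintf("generate_dataset: output directory '%s' is not writable", dir),
         call. = FALSE)
  }
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    s <- generate_sample(params, i)
    img_path <- file.path(dir, sprintf("img_%04d.png", i))
    write_image(s$image, img_path)
    mask_paths <- vapply(COMBOS, function(cmb) {
      p <- file.path(dir, sprintf("mask_%04d_%s.png", i, cmb))
      write_mask(s$masks[[cmb]], p)
      p
    }, character(1))
    rows[[i]] <- data.frame(
      image_path = img_path,
      mask_RG = mask_paths["RG"], mask_RB = mask_paths["RB"],
      mask_GB = mask_paths["GB"], mask_RGB = mask_paths["RGB"],
      seed = params$rng_seed, index = i
    )
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(params), file.path(dir, "params.yaml"))
  invisible(manifest)
}
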