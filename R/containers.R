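#' Three-channel fluorescence image container
#'
#' Wraps an H x W x 3 numeric array of intensities in `[0, 1]` (channels in
#' R, G, B order) together with optional acquisition metadata such as the
#' disease group or the physical side length of the imaged field.  The
#' coordinate convention is row-major with the origin at the top-left pixel.
#'
#' @param data numeric array of dimension `c(H, W, 3)` with values in `[0, 1]`.
#' @param meta named list of optional metadata (e.g. `native_size`,
#'   `physical_size_um`, `disease`).
#' @return An object of class `fluorescence_image` (an array with a `meta`
#'   attribute).
#' @export
fluorescence_image <- function(data, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L) {
    stop("fluorescence_image: 'data' must be an H x W x 3 array", call. = FALSE)
  }
  if (anyNA(data) || min(data) < 0 || max(data) > 1) {
    stop("fluorescence_image: intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(data, meta = meta, class = c("fluorescence_image", "array"))
}

#' @export
print.fluorescence_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<fluorescence_image %d x %d x %d, range [%.3f, %.3f]>\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

#' Four aligned channel-combination masks
#'
#' A named list of four binary (0/1 integer) matrices, one per channel
#' combination, in the canonical order [COMBOS].  Each mask marks the pixels
#' with significant joint signal in its combination inside a tangle core.
#'
#' @param masks named list of binary matrices with names `RG, RB, GB, RGB`
#'   (any order; they are reordered canonically), all of identical dimension.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(masks) {
  if (!is.list(masks) || !setequal(names(masks), COMBOS)) {
    stop("mask_set: need a named list with masks RG, RB, GB, RGB", call. = FALSE)
  }
  masks <- masks[COMBOS]
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) {
    stop("mask_set: all masks must share one dimension", call. = FALSE)
  }
  masks <- lapply(masks, function(m) {
    if (!all(m %in% c(0, 1))) {
      stop("mask_set: masks must be binary (0/1)", call. = FALSE)
    }
    storage.mode(m) <- "integer"
    m
  })
  structure(masks, class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  d <- dim(x[[1]])
  cov <- vapply(x, function(m) 100 * mean(m), numeric(1))
  cat(sprintf("<mask_set %d x %d; %% positive: %s>\n", d[1], d[2],
              paste(sprintf("%s %.2f", names(x), cov), collapse = ", ")))
  invisible(x)
}

#' Segmentation result: probability maps plus binarized masks
#'
#' @param prob_maps named list of probability matrices in `[0, 1]`, one per
#'   channel combination.
#' @param threshold binarization cutoff; a pixel enters the binary mask iff
#'   its probability is strictly greater than the threshold.
#' @return An object of class `segmentation_result` with elements
#'   `prob_maps`, `binary_masks` (a [mask_set]) and `combo_order`.
#' @export
segmentation_result <- function(prob_maps, threshold = 0.5) {
  stopifnot(setequal(names(prob_maps), COMBOS))
  prob_maps <- prob_maps[COMBOS]
  for (p in prob_maps) {
    if (min(p) < 0 || max(p) > 1) {
      stop("segmentation_result: probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(
    prob_maps    = prob_maps,
    binary_masks = mask_set(lapply(prob_maps, binarize, threshold = threshold)),
    combo_order  = COMBOS,
    threshold    = threshold
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result %s, threshold %g>\n",
              paste(dim(x$prob_maps[[1]]), collapse = " x "), x$threshold))
  print(x$binary_masks)
  invisible(x)
}

#' Threshold a probability map into a binary mask
#'
#' Applies a strict greater-than comparison: ties at exactly the threshold
#' are excluded from the segmentation.  Idempotent on already-binary input
#' for any threshold in (0, 1).
#'
#' @param x numeric matrix or array of values in `[0, 1]`.
#' @param threshold cutoff in (0, 1).
#' @return Integer 0/1 object of the same shape.
#' @export
binarize <- function(x, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop_config("threshold", "must lie in (0, 1)")
  }
  out <- (x > threshold) * 1L
  storage.mode(out) <- "integer"
  out
}
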