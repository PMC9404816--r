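#' Quantify one binary mask as a pixel fraction
#'
#' Counts the segmented (value 1) pixels and divides by the mask's own
#' total pixel count (65,536 for the 256 x 256 working resolution), giving
#' the fluorescence percentage of that channel combination.
#'
#' @param mask binary 0/1 matrix.
#' @return A list with `count`, `total_pixels` and `percentage`
#'   (`100 * count / total_pixels`, exact).
#' @export
quantify_mask <- function(mask) {
  if (!all(mask %in% c(0, 1))) {
    stop("quantify_mask: mask must be binary (0/1)", call. = FALSE)
  }
  count <- sum(mask == 1)
  total <- length(mask)
  list(count = as.integer(count), total_pixels = as.integer(total),
       percentage = 100 * count / total)
}

# shared builder for quantification reports
.quant_report <- function(masks, image_id, source) {
  rows <- do.call(rbind, lapply(COMBOS, function(cmb) {
    q <- quantify_mask(masks[[cmb]])
    data.frame(image_id = image_id, combo = cmb, pixel_count = q$count,
               total_pixels = q$total_pixels, percent = q$percentage)
  }))
  structure(rows, source = source, class = c("quant_report", "data.frame"))
}

#' Fluorescence quantification report for one image
#'
#' Runs the network on the image, thresholds each probability map, and
#' reports the segmented-pixel percentage of every channel combination in
#' canonical order (RG, RB, GB, RGB).
#'
#' @param model a trained `ssunet` with four decoders.
#' @param image a [fluorescence_image] at the model's input size.
#' @param image_id identifier carried into the report.
#' @return An object of class `quant_report`: a data frame with columns
#'   `image_id, combo, pixel_count, total_pixels, percent` and attribute
#'   `source = "model prediction"`.
#' @export
quantify_image <- function(model, image, image_id = NA) {
  stopifnot(inherits(model, "ssunet"))
  if (model$config$n_outputs != 4L) {
    stop("quantify_image: quantification needs the four-output model", call. = FALSE)
  }
  seg <- predict(model, image)
  .quant_report(seg$binary_masks, image_id, source = "model prediction")
}

#' Fluorescence quantification from ground-truth masks
#'
#' The same report as [quantify_image()] but computed directly from label
#' masks, bypassing the model.
#'
#' @param masks a [mask_set].
#' @param image_id identifier carried into the report.
#' @return A `quant_report` with attribute `source = "ground-truth mask"`.
#' @export
quantify_masks <- function(masks, image_id = NA) {
  stopifnot(inherits(masks, "mask_set"))
  .quant_report(masks, image_id, source = "ground-truth mask")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("Fluorescence quantification (%s), %d total pixels:\n",
              attr(x, "source"), x$total_pixels[1]))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-4s %6d px  %.2f%%\n", x$combo[i], x$pixel_count[i], x$percent[i]))
  }
  invisible(x)
}
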