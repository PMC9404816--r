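#' Read a three-channel fluorescence image
#'
#' Decodes a PNG/TIFF/JPEG file into a [fluorescence_image] with intensities
#' scaled to `[0, 1]`.  Single-channel (grayscale) files are rejected: the
#' quantification protocol is defined on three-colour acquisitions.  The
#' native pixel size is recorded in the image metadata; if `resize_to` is
#' given the raster is resampled (bilinear) to that side length, as done
#' when 512 x 512 acquisitions are brought to the 256 x 256 network input.
#'
#' @param path image file path.
#' @param resize_to optional target side length in pixels.
#' @return A [fluorescence_image].
#' @export
read_image <- function(path, resize_to = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("read_image: file '%s' does not exist", path), call. = FALSE)
  }
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) < 3L || d[3] < 3L) {
    stop(sprintf("read_image: '%s' has %d channel(s); a 3-channel image is required",
                 path, if (length(d) < 3L) 1L else d[3]), call. = FALSE)
  }
  arr <- as.array(img)[, , 1:3, drop = FALSE]   # drop any alpha channel
  arr <- aperm(arr, c(2L, 1L, 3L))              # EBImage stores x,y; we use row,col
  arr <- pmin(pmax(arr, 0), 1)
  native <- dim(arr)[1:2]
  if (!is.null(resize_to) && !all(native == resize_to)) {
    arr <- resize_array(arr, resize_to, bilinear = TRUE)
  }
  fluorescence_image(arr, meta = list(native_size = native, path = path))
}

#' Write a fluorescence image as an 8-bit RGB PNG (or JPEG/TIFF by extension)
#'
#' @param image a [fluorescence_image] or H x W x 3 array in `[0, 1]`.
#' @param path output path; the format follows the file extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  arr <- aperm(unclass(image)[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary segmentation mask
#'
#' Decodes a single-channel (or RGB, collapsed by Rec.601 luminance) mask
#' file and binarizes at 50% of the dynamic range, which tolerates the
#' compression artifacts of masks stored as JPEG.
#'
#' @param path mask file path.
#' @return An integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_mask: file '%s' does not exist", path), call. = FALSE)
  }
  img <- as.array(EBImage::readImage(path))
  if (length(dim(img)) == 3L) {
    w <- c(0.299, 0.587, 0.114)[seq_len(min(3L, dim(img)[3]))]
    img <- apply(sweep(img[, , seq_along(w), drop = FALSE], 3L, w / sum(w), `*`),
                 c(1L, 2L), sum)
  }
  m <- (t(img) >= 0.5) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Write a binary mask as a single-channel 8-bit PNG with values 0/255
#'
#' @param mask integer/numeric 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) {
    stop("write_mask: mask must be binary (0/1)", call. = FALSE)
  }
  EBImage::writeImage(EBImage::Image(t(mask * 1.0)), path, bits.per.sample = 8L)
  invisible(path)
}

# Resample an H x W (x C) array to a square side; bilinear for intensity
# rasters, nearest-neighbour for label rasters (then re-binarize upstream).
resize_array <- function(arr, side, bilinear = TRUE) {
  is_mat <- is.matrix(arr)
  a <- if (is_mat) t(arr) else aperm(arr, c(2L, 1L, 3L))
  img <- EBImage::Image(a, colormode = if (is_mat) "Grayscale" else "Color")
  out <- EBImage::resize(img, w = side, h = side,
                         filter = if (bilinear) "bilinear" else "none")
  out <- as.array(out)
  if (is_mat) t(out) else aperm(out, c(2L, 1L, 3L))
}

#' Resize a sample (image + masks) to a target side length
#'
#' Intensities are resampled bilinearly; masks use nearest-neighbour
#' resampling and are re-binarized at half range so they stay strictly 0/1.
#'
#' @param image a [fluorescence_image].
#' @param masks a [mask_set].
#' @param side target side length in pixels (e.g. 256 for 512 x 512 input).
#' @return A list with resized `image` and `masks`.
#' @export
resize_sample <- function(image, masks, side) {
  arr <- pmin(pmax(resize_array(unclass(image), side, bilinear = TRUE), 0), 1)
  new_masks <- lapply(masks, function(m) {
    binarize(resize_array(m * 1.0, side, bilinear = FALSE), 0.5)
  })
  list(image = fluorescence_image(arr, meta = attr(image, "meta")),
       masks = mask_set(new_masks))
}

#' Load a dataset manifest and its samples
#'
#' Reads the CSV manifest written by [generate_dataset()] or
#' [augment_dataset()] and loads every image and mask set.
#'
#' @param manifest_path path to `manifest.csv`; relative file paths in the
#'   manifest are resolved against its directory.
#' @param resize_to optional side length applied to every sample on load.
#' @return A list of samples, each `list(image, masks, index)`.
#' @export
read_dataset <- function(manifest_path, resize_to = NULL) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("read_dataset: manifest '%s' does not exist", manifest_path),
         call. = FALSE)
  }
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  lapply(seq_len(nrow(man)), function(i) {
    image <- read_image(resolve(man$image_path[i]))
    masks <- mask_set(structure(lapply(COMBOS, function(cmb) {
      read_mask(resolve(man[[paste0("mask_", cmb)]][i]))
    }), names = COMBOS))
    if (!is.null(resize_to) && nrow(image) != resize_to) {
      s <- resize_sample(image, masks, resize_to)
      image <- s$image; masks <- s$masks
    }
    list(image = image, masks = masks, index = man$index[i])
  })
}

#' Assemble a full run configuration
#'
#' Bundles paths plus the model, training, augmentation and synthetic-data
#' parameter blocks into one serializable object.  [read_run_config()]
#' rejects unknown keys so that config-file typos fail loudly.
#'
#' @param data_root,output_root,weights_dir filesystem paths.
#' @param model a [model_config].
#' @param training a [train_config].
#' @param augment an [augment_params].
#' @param synthetic a [synthetic_params].
#' @param log_level one of "info", "debug", "quiet".
#' @return An object of class `run_config`.
#' @export
run_config <- function(data_root = "data", output_root = "output",
                       weights_dir = "weights",
                       model = model_config(), training = train_config(),
                       augment = augment_params(), synthetic = synthetic_params(),
                       log_level = "info") {
  if (!log_level %in% c("info", "debug", "quiet")) {
    stop_config("log_level", "must be one of info, debug, quiet")
  }
  structure(list(
    data_root = data_root, output_root = output_root, weights_dir = weights_dir,
    model = model, training = training, augment = augment, synthetic = synthetic,
    log_level = log_level
  ), class = "run_config")
}

#' Serialize a run configuration to YAML
#'
#' @param config a [run_config].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Parse a run configuration from YAML, rejecting unknown keys
#'
#' @param path YAML file written by [write_run_config()] (or hand-edited).
#' @return A [run_config]; `parse(serialize(config))` equals `config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- run_config()
  check_keys <- function(got, allowed, where) {
    extra <- setdiff(names(got), allowed)
    if (length(extra) > 0) {
      stop(sprintf("read_run_config: unknown key(s) in %s: %s", where,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  check_keys(raw, names(defaults), "config root")
  blocks <- list(model = model_config, training = train_config,
                 augment = augment_params, synthetic = synthetic_params)
  for (b in names(blocks)) {
    if (!is.null(raw[[b]])) {
      check_keys(raw[[b]], names(defaults[[b]]), b)
      raw[[b]] <- do.call(blocks[[b]], raw[[b]])
    }
  }
  args <- utils::modifyList(lapply(unclass(defaults), identity),
                            raw[!vapply(raw, is.null, logical(1))])
  do.call(run_config, args)
}

# Append a timestamped line to a run log (one event per line).
log_line <- function(log_file, ..., level = "info") {
  if (is.null(log_file)) return(invisible(NULL))
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(..., collapse = ""))
  cat(line, "\n", file = log_file, append = TRUE, sep = "")
  invisible(line)
}
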