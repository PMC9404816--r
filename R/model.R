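#' Architecture configuration of the semi-Siamese U-Net
#'
#' One shared contracting (encoder) path and `n_outputs` parallel expanding
#' (decoder) paths.  Each encoder level applies two same-padded stride-1
#' convolutions (ReLU); a 2 x 2 max-pool followed by dropout sits between
#' levels.  The filter schedule doubles per level from `base_filters`
#' (16/32/64/128/256 at default).  Each decoder level nearest-upsamples by 2,
#' concatenates its own copy of the matching encoder feature map, applies two
#' convolutions and dropout; a final 1 x 1 convolution with sigmoid yields
#' each probability map.  With `n_outputs = 1` the builder produces a
#' classical single-decoder U-Net with the same hyperparameters.
#'
#' @param input_size input side length in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @param input_channels number of input channels (3 for RGB fluorescence).
#' @param n_outputs number of decoders (4 = one per channel combination).
#' @param depth encoder levels including the bottleneck.
#' @param base_filters filters at level 1; level L has `base_filters * 2^(L-1)`.
#' @param kernel_size square convolution kernel side (odd).
#' @param dropout_rate dropout fraction in `[0, 1)`.
#' @param threshold binarization cutoff in (0, 1) applied to the sigmoid
#'   probability maps (strictly greater-than).
#' @param init_scheme `"glorot_uniform"` (default: uniform with the fan-based
#'   Glorot limit `sqrt(6 / (fan_in + fan_out))`) or `"uniform_pm1"` (fixed
#'   limits -1 to 1).
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_size = 256L, input_channels = 3L,
                         n_outputs = 4L, depth = 5L, base_filters = 16L,
                         kernel_size = 5L, dropout_rate = 0.2,
                         threshold = 0.5,
                         init_scheme = c("glorot_uniform", "uniform_pm1")) {
  init_scheme <- match.arg(init_scheme)
  if (depth < 2) stop_config("depth", "must be >= 2")
  if (input_size %% 2^(depth - 1) != 0) {
    stop_config("input_size",
                sprintf("must be divisible by 2^(depth-1) = %d", 2^(depth - 1)))
  }
  if (n_outputs < 1) stop_config("n_outputs", "must be >= 1")
  if (kernel_size %% 2 != 1 || kernel_size < 1) {
    stop_config("kernel_size", "must be a positive odd integer")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_config("dropout_rate", "must lie in [0, 1)")
  }
  if (threshold <= 0 || threshold >= 1) stop_config("threshold", "must lie in (0, 1)")
  structure(list(
    input_size = as.integer(input_size), input_channels = as.integer(input_channels),
    n_outputs = as.integer(n_outputs), depth = as.integer(depth),
    base_filters = as.integer(base_filters), kernel_size = as.integer(kernel_size),
    dropout_rate = dropout_rate, threshold = threshold, init_scheme = init_scheme
  ), class = "model_config")
}

# filters at encoder level L
.filters_at <- function(config, L) config$base_filters * 2L^(L - 1L)

# one (k*k*cin) x cout weight matrix plus bias, under the configured scheme
.init_conv <- function(k, cin, cout, scheme) {
  fan_in <- k * k * cin
  fan_out <- k * k * cout
  limit <- if (scheme == "uniform_pm1") 1 else sqrt(6 / (fan_in + fan_out))
  list(W = matrix(runif(fan_in * cout, -limit, limit), fan_in, cout),
       b = numeric(cout))
}

# the ordered conv-layer schedule: name, kernel, cin, cout
.layer_schedule <- function(config) {
  k <- config$kernel_size
  sched <- list()
  cin <- config$input_channels
  for (L in seq_len(config$depth)) {
    f <- .filters_at(config, L)
    sched[[length(sched) + 1L]] <- list(name = sprintf("enc%d_c1", L), k = k, cin = cin, cout = f)
    sched[[length(sched) + 1L]] <- list(name = sprintf("enc%d_c2", L), k = k, cin = f, cout = f)
    cin <- f
  }
  for (d in seq_len(config$n_outputs)) {
    prev <- .filters_at(config, config$depth)
    for (L in rev(seq_len(config$depth - 1L))) {
      f <- .filters_at(config, L)
      sched[[length(sched) + 1L]] <- list(name = sprintf("dec%d_l%d_c1", d, L),
                                          k = k, cin = prev + f, cout = f)
      sched[[length(sched) + 1L]] <- list(name = sprintf("dec%d_l%d_c2", d, L),
                                          k = k, cin = f, cout = f)
      prev <- f
    }
    sched[[length(sched) + 1L]] <- list(name = sprintf("out%d", d), k = 1L,
                                        cin = config$base_filters, cout = 1L)
  }
  sched
}

#' Build a semi-Siamese U-Net
#'
#' Materializes all convolution weights from `init_seed` under the
#' configured initialization scheme.  The same seed and configuration always
#' produce bit-identical weights, so an initialization can be persisted once
#' and shared across cross-validation folds.
#'
#' @param config a [model_config].
#' @param init_seed integer seed for the weight initializer.
#' @return An object of class `ssunet`: a list with `config` and `params`
#'   (flat named list of weight matrices and bias vectors).
#' @export
build_model <- function(config = model_config(), init_seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  params <- with_seed(derive_seed(init_seed, 0L), {
    out <- list()
    for (lay in .layer_schedule(config)) {
      wb <- .init_conv(lay$k, lay$cin, lay$cout, config$init_scheme)
      out[[paste0(lay$name, "_W")]] <- wb$W
      out[[paste0(lay$name, "_b")]] <- wb$b
    }
    out
  })
  structure(list(config = config, params = params), class = "ssunet")
}

#' Count trainable parameters
#'
#' @param model an [build_model()] network.
#' @return Total number of trainable scalars (weights + biases).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ssunet"))
  sum(vapply(model$params, length, numeric(1)))
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

# concatenate two H x W x C cubes along the channel axis
cat_channels <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

# inverted-dropout mask (scales kept units by 1/(1-rate))
drop_mask <- function(dims, rate) {
  array((runif(prod(dims)) >= rate) / (1 - rate), dim = dims)
}

# Forward pass.  With training = TRUE, dropout is active and all
# intermediate activations needed by nn_backward are cached.
nn_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  p <- model$params
  k <- cfg$kernel_size
  rate <- cfg$dropout_rate
  use_drop <- training && rate > 0

  enc <- vector("list", cfg$depth)
  h <- x
  for (L in seq_len(cfg$depth)) {
    nm <- sprintf("enc%d", L)
    x1 <- h
    a1 <- relu(cpp_conv_fwd(x1, p[[paste0(nm, "_c1_W")]], p[[paste0(nm, "_c1_b")]], k))
    a2 <- relu(cpp_conv_fwd(a1, p[[paste0(nm, "_c2_W")]], p[[paste0(nm, "_c2_b")]], k))
    lev <- list(x1 = x1, a1 = a1, a2 = a2)
    if (L < cfg$depth) {
      mp <- cpp_maxpool_fwd(a2)
      h <- mp$out
      lev$pool_idx <- mp$idx
      if (use_drop) {
        lev$dmask <- drop_mask(dim(h), rate)
        h <- h * lev$dmask
      }
    }
    enc[[L]] <- lev
  }
  bottleneck <- enc[[cfg$depth]]$a2

  dec <- vector("list", cfg$n_outputs)
  probs <- vector("list", cfg$n_outputs)
  for (d in seq_len(cfg$n_outputs)) {
    h <- bottleneck
    levs <- vector("list", cfg$depth - 1L)
    for (L in rev(seq_len(cfg$depth - 1L))) {
      nm <- sprintf("dec%d_l%d", d, L)
      up <- cpp_upsample2_fwd(h)
      catx <- cat_channels(up, enc[[L]]$a2)
      a1 <- relu(cpp_conv_fwd(catx, p[[paste0(nm, "_c1_W")]], p[[paste0(nm, "_c1_b")]], k))
      a2 <- relu(cpp_conv_fwd(a1, p[[paste0(nm, "_c2_W")]], p[[paste0(nm, "_c2_b")]], k))
      lev <- list(up_ch = dim(up)[3], catx = catx, a1 = a1, a2 = a2)
      h <- a2
      if (use_drop) {
        lev$dmask <- drop_mask(dim(h), rate)
        h <- h * lev$dmask
      }
      lev$h_out <- h
      levs[[L]] <- lev
    }
    logits <- cpp_conv_fwd(h, p[[sprintf("out%d_W", d)]], p[[sprintf("out%d_b", d)]], 1L)
    probs[[d]] <- sigmoid(logits[, , 1L])
    dec[[d]] <- list(levels = levs, head_in = h, logits = logits)
  }
  list(probs = probs, cache = list(x = x, enc = enc, dec = dec, use_drop = use_drop))
}

# Reverse-mode gradients.  dlogits: list (length n_outputs) of H x W
# matrices, the loss gradient at each decoder's pre-sigmoid output.
nn_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  k <- cfg$kernel_size
  grads <- lapply(model$params, function(x) x * 0)
  dskip <- vector("list", cfg$depth)           # grads flowing into encoder skips
  d_bottleneck <- array(0, dim = dim(cache$enc[[cfg$depth]]$a2))

  for (d in seq_len(cfg$n_outputs)) {
    dc <- cache$dec[[d]]
    dl <- array(dlogits[[d]], dim = c(dim(dlogits[[d]]), 1L))
    bw <- cpp_conv_bwd(dc$head_in, p[[sprintf("out%d_W", d)]], dl, 1L)
    grads[[sprintf("out%d_W", d)]] <- grads[[sprintf("out%d_W", d)]] + bw$dw
    grads[[sprintf("out%d_b", d)]] <- grads[[sprintf("out%d_b", d)]] + as.numeric(bw$db)
    g <- bw$dx
    for (L in seq_len(cfg$depth - 1L)) {
      lev <- dc$levels[[L]]
      nm <- sprintf("dec%d_l%d", d, L)
      if (!is.null(lev$dmask)) g <- g * lev$dmask
      g <- g * (lev$a2 > 0)
      bw2 <- cpp_conv_bwd(lev$a1, p[[paste0(nm, "_c2_W")]], g, k)
      grads[[paste0(nm, "_c2_W")]] <- grads[[paste0(nm, "_c2_W")]] + bw2$dw
      grads[[paste0(nm, "_c2_b")]] <- grads[[paste0(nm, "_c2_b")]] + as.numeric(bw2$db)
      g <- bw2$dx * (lev$a1 > 0)
      bw1 <- cpp_conv_bwd(lev$catx, p[[paste0(nm, "_c1_W")]], g, k)
      grads[[paste0(nm, "_c1_W")]] <- grads[[paste0(nm, "_c1_W")]] + bw1$dw
      grads[[paste0(nm, "_c1_b")]] <- grads[[paste0(nm, "_c1_b")]] + as.numeric(bw1$db)
      cu <- lev$up_ch
      dup <- bw1$dx[, , seq_len(cu), drop = FALSE]
      dsk <- bw1$dx[, , cu + seq_len(dim(bw1$dx)[3] - cu), drop = FALSE]
      dskip[[L]] <- if (is.null(dskip[[L]])) dsk else dskip[[L]] + dsk
      g <- cpp_upsample2_bwd(dup)
    }
    d_bottleneck <- d_bottleneck + g
  }

  g_below <- NULL                              # grad wrt the pooled+dropped input of level L+1
  for (L in rev(seq_len(cfg$depth))) {
    lev <- cache$enc[[L]]
    nm <- sprintf("enc%d", L)
    if (L == cfg$depth) {
      g <- d_bottleneck
    } else {
      gp <- g_below
      if (!is.null(lev$dmask)) gp <- gp * lev$dmask
      g <- cpp_maxpool_bwd(gp, lev$pool_idx, dim(lev$a2)[1], dim(lev$a2)[2])
      if (!is.null(dskip[[L]])) g <- g + dskip[[L]]
    }
    g <- g * (lev$a2 > 0)
    bw2 <- cpp_conv_bwd(lev$a1, p[[paste0(nm, "_c2_W")]], g, k)
    grads[[paste0(nm, "_c2_W")]] <- grads[[paste0(nm, "_c2_W")]] + bw2$dw
    grads[[paste0(nm, "_c2_b")]] <- grads[[paste0(nm, "_c2_b")]] + as.numeric(bw2$db)
    g <- bw2$dx * (lev$a1 > 0)
    bw1 <- cpp_conv_bwd(lev$x1, p[[paste0(nm, "_c1_W")]], g, k)
    grads[[paste0(nm, "_c1_W")]] <- grads[[paste0(nm, "_c1_W")]] + bw1$dw
    grads[[paste0(nm, "_c1_b")]] <- grads[[paste0(nm, "_c1_b")]] + as.numeric(bw1$db)
    g_below <- bw1$dx
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the network on one image
#'
#' Forward pass with dropout inactive, followed by strict greater-than
#' thresholding of each sigmoid probability map.
#'
#' @param object an `ssunet` network.
#' @param image a [fluorescence_image] (or H x W x C array in `[0, 1]`) whose
#'   spatial size equals `config$input_size`.
#' @param ... unused.
#' @return With four decoders, a [segmentation_result] keyed RG, RB, GB,
#'   RGB; otherwise a list with `prob_maps` and `binary_masks` named
#'   `out1..outN`.
#' @export
predict.ssunet <- function(object, image, ...) {
  cfg <- object$config
  x <- unclass(image)
  d <- dim(x)
  if (is.null(d) || length(d) != 3L || d[1] != cfg$input_size ||
      d[2] != cfg$input_size || d[3] != cfg$input_channels) {
    stop(sprintf(
      "predict: expected a %d x %d x %d input, received %s",
      cfg$input_size, cfg$input_size, cfg$input_channels,
      paste(d %||% length(x), collapse = " x ")), call. = FALSE)
  }
  fw <- nn_forward(object, x, training = FALSE)
  if (cfg$n_outputs == 4L) {
    segmentation_result(structure(fw$probs, names = COMBOS), cfg$threshold)
  } else {
    nm <- paste0("out", seq_len(cfg$n_outputs))
    list(prob_maps = structure(fw$probs, names = nm),
         binary_masks = structure(lapply(fw$probs, binarize, threshold = cfg$threshold),
                                  names = nm),
         combo_order = nm)
  }
}

#' Architecture summary as a layer table
#'
#' @param object an `ssunet` network.
#' @param ... unused.
#' @return A data frame with one row per convolution layer: name, output
#'   spatial side, output channels, parameter count.
#' @export
summary.ssunet <- function(object, ...) {
  cfg <- object$config
  side_at <- function(L) cfg$input_size / 2L^(L - 1L)
  rows <- lapply(.layer_schedule(cfg), function(lay) {
    L <- if (grepl("^enc", lay$name)) {
      as.integer(sub("enc(\\d+)_.*", "\\1", lay$name))
    } else if (grepl("^dec", lay$name)) {
      as.integer(sub("dec\\d+_l(\\d+)_.*", "\\1", lay$name))
    } else 1L
    data.frame(layer = lay$name, side = side_at(L), channels = lay$cout,
               params = lay$k^2 * lay$cin * lay$cout + lay$cout)
  })
  out <- do.call(rbind, rows)
  attr(out, "total_params") <- sum(out$params)
  out
}

#' @export
print.ssunet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ssunet: %d encoder level(s), %d decoder(s), input %d x %d x %d, %s params>\n",
    cfg$depth, cfg$n_outputs, cfg$input_size, cfg$input_size,
    cfg$input_channels, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Persist / restore network weights
#'
#' Weights are stored with `saveRDS` and validated on load against the
#' receiving model's parameter names and shapes, so an initialization
#' materialized once can be reloaded bit-identically in every fold.
#'
#' @param model an `ssunet`.
#' @param path checkpoint file path.
#' @return `save_weights`: `path`, invisibly.  `load_weights`: the model
#'   with restored parameters.
#' @export
save_weights <- function(model, path) {
  stopifnot(inherits(model, "ssunet"))
  saveRDS(model$params, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  params <- readRDS(path)
  if (!identical(names(params), names(model$params))) {
    stop("load_weights: checkpoint does not match the model's layer layout",
         call. = FALSE)
  }
  model$params <- params
  model
}
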