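#' Training protocol configuration
#'
#' Deterministic k-fold cross-validation with shared initial weights,
#' optimizing the pixel-mean binary cross-entropy across the four outputs
#' with Adam (only the learning rate is tuned; the moment parameters keep
#' their conventional defaults beta1 = 0.9, beta2 = 0.999, eps = 1e-8).
#'
#' @param k_folds number of cross-validation folds (>= 2 for
#'   [cross_validate()]).
#' @param learning_rate Adam step size (default 5e-4).
#' @param epochs training epochs per fold.
#' @param batch_size mini-batch size.
#' @param split_seed,init_seed,shuffle_seed integer seeds governing the fold
#'   assignment, the shared weight initialization, and the per-epoch batch
#'   shuffling (plus dropout draws), respectively.
#' @param resize_to working resolution in pixels; native 512 x 512
#'   acquisitions are resized to 256 x 256 before training.
#' @param augment logical; expand each training fold fourfold with
#'   [augment_fold()] before training (validation data are never augmented).
#' @return An object of class `train_config`.
#' @export
train_config <- function(k_folds = 5L, learning_rate = 5e-4, epochs = 50L,
                         batch_size = 4L, split_seed = 1L, init_seed = 1L,
                         shuffle_seed = 1L, resize_to = 256L, augment = TRUE) {
  if (k_folds < 2) stop_config("k_folds", "must be >= 2")
  if (learning_rate < 0) stop_config("learning_rate", "must be >= 0")
  if (epochs < 1) stop_config("epochs", "must be >= 1")
  if (batch_size < 1) stop_config("batch_size", "must be >= 1")
  structure(list(
    k_folds = as.integer(k_folds), learning_rate = as.numeric(learning_rate),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    split_seed = as.integer(split_seed), init_seed = as.integer(init_seed),
    shuffle_seed = as.integer(shuffle_seed), resize_to = as.integer(resize_to),
    augment = isTRUE(augment)
  ), class = "train_config")
}

#' Deterministic k-fold partition
#'
#' Shuffles `1:n_items` under `split_seed` and partitions it into `k`
#' validation sets whose sizes differ by at most one; each item appears in
#' exactly one validation set.  For 97 items and 5 folds this gives
#' validation sizes 19/19/19/20/20, so three folds train on 78 images (80%)
#' and validate on 19 (20%).
#'
#' @param n_items number of items to split.
#' @param config a [train_config] (uses `k_folds` and `split_seed`), or an
#'   integer fold count.
#' @param split_seed seed used when `config` is given as an integer.
#' @return A list of `k` elements, each `list(train = indices, val = indices)`.
#' @export
kfold_split <- function(n_items, config = train_config(), split_seed = 1L) {
  if (is.numeric(config)) config <- train_config(k_folds = config, split_seed = split_seed)
  k <- config$k_folds
  if (n_items < k) {
    stop_config("k_folds", sprintf("cannot split %d items into %d folds", n_items, k))
  }
  perm <- with_seed(derive_seed(config$split_seed, 2L), sample.int(n_items))
  sizes <- rep(n_items %/% k, k)
  extra <- n_items %% k
  if (extra > 0) sizes[(k - extra + 1):k] <- sizes[(k - extra + 1):k] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(k), function(i) {
    val <- sort(perm[starts[i]:ends[i]])
    list(train = setdiff(seq_len(n_items), val), val = val)
  })
}

#' Binary cross-entropy loss across the four outputs
#'
#' The pixel-mean of `-(y log(p) + (1 - y) log(1 - p))`, averaged over the
#' outputs.  Predictions are clipped to `[eps, 1 - eps]` before the logs.
#'
#' @param prediction list of probability matrices (or a
#'   [segmentation_result], whose `prob_maps` are used).
#' @param truth a [mask_set] (or list of binary matrices) of matching order
#'   and shapes.
#' @param eps clipping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(prediction, truth, eps = 1e-7) {
  if (inherits(prediction, "segmentation_result")) prediction <- prediction$prob_maps
  if (length(prediction) != length(truth)) {
    stop("bce_loss: prediction and truth must have the same number of outputs",
         call. = FALSE)
  }
  per_output <- vapply(seq_along(prediction), function(i) {
    p <- pmin(pmax(prediction[[i]], eps), 1 - eps)
    y <- truth[[i]]
    if (!identical(dim(p), dim(y))) {
      stop(sprintf("bce_loss: output %d shape mismatch: %s vs %s", i,
                   paste(dim(p), collapse = "x"), paste(dim(y), collapse = "x")),
           call. = FALSE)
    }
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }, numeric(1))
  mean(per_output)
}

# --- Adam optimizer over the flat parameter list ---------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# image (+ mask) accessors tolerant to both sample layout and bare arrays
.sample_x <- function(s) unclass(s$image)
.sample_y <- function(s) lapply(s$masks, function(m) m * 1.0)

#' Train the network on one fold
#'
#' Mini-batch Adam on the four-output binary cross-entropy.  Batches are
#' reshuffled every epoch under `shuffle_seed`; dropout is active during
#' training.  The per-epoch mean training loss is recorded; if validation
#' samples are supplied, per-image-per-output metric records are computed
#' with the evaluation module on the trained weights.
#'
#' @param model an `ssunet` carrying the (shared) initial weights.
#' @param train_samples non-empty list of samples `list(image, masks)` at the
#'   model's input size (already augmented, if desired).
#' @param config a [train_config].
#' @param val_samples optional validation samples (never augmented).
#' @param fold_index bookkeeping index carried into the result.
#' @param log_file optional path for one-line-per-epoch progress logging.
#' @return An object of class `fold_result`: `list(fold_index, model,
#'   loss_history, records)`.
#' @export
train_fold <- function(model, train_samples, config = train_config(),
                       val_samples = NULL, fold_index = 1L, log_file = NULL) {
  stopifnot(inherits(model, "ssunet"), inherits(config, "train_config"))
  if (length(train_samples) == 0) {
    stop("train_fold: training set is empty", call. = FALSE)
  }
  d1 <- dim(.sample_x(train_samples[[1]]))
  if (d1[1] != model$config$input_size || d1[2] != model$config$input_size ||
      d1[3] != model$config$input_channels) {
    stop(sprintf("train_fold: samples are %s but the model expects %d x %d x %d",
                 paste(d1, collapse = " x "), model$config$input_size,
                 model$config$input_size, model$config$input_channels),
         call. = FALSE)
  }
  n <- length(train_samples)
  n_out <- model$config$n_outputs
  npx <- model$config$input_size^2
  eps <- 1e-7
  state <- adam_init(model$params)
  loss_history <- numeric(config$epochs)

  with_seed(derive_seed(config$shuffle_seed, fold_index), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1L, n, by = config$batch_size)
      epoch_losses <- numeric(0)
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
        grads <- NULL
        batch_loss <- 0
        for (i in idx) {
          s <- train_samples[[i]]
          fw <- nn_forward(model, .sample_x(s), training = TRUE)
          y <- .sample_y(s)
          dlogits <- vector("list", n_out)
          loss_i <- 0
          for (o in seq_len(n_out)) {
            pr <- pmin(pmax(fw$probs[[o]], eps), 1 - eps)
            loss_i <- loss_i - mean(y[[o]] * log(pr) + (1 - y[[o]]) * log(1 - pr))
            # d(mean BCE over outputs)/dlogit, including the 1/batch factor
            dlogits[[o]] <- (fw$probs[[o]] - y[[o]]) / (npx * n_out * length(idx))
          }
          batch_loss <- batch_loss + loss_i / n_out
          g <- nn_backward(model, fw$cache, dlogits)
          grads <- if (is.null(grads)) g else Map(`+`, grads, g)
        }
        if (config$learning_rate > 0) {
          upd <- adam_step(model$params, grads, state, config$learning_rate)
          model$params <- upd$params
          state <- upd$state
        }
        epoch_losses <- c(epoch_losses, batch_loss / length(idx))
      }
      loss_history[epoch] <- mean(epoch_losses)
      log_line(log_file, sprintf("fold %d epoch %d mean_loss %.6f",
                                 fold_index, epoch, loss_history[epoch]))
    }
  })

  records <- NULL
  if (!is.null(val_samples) && length(val_samples) > 0) {
    records <- do.call(rbind, lapply(seq_along(val_samples), function(i) {
      s <- val_samples[[i]]
      seg <- predict(model, s$image)
      metric_records(s$masks, seg$binary_masks,
                     image_id = s$index %||% i)
    }))
  }
  structure(list(fold_index = fold_index, model = model,
                 loss_history = loss_history, records = records),
            class = "fold_result")
}

#' Full cross-validated training protocol
#'
#' Builds the network once from `init_seed`, persists the initial weights,
#' and trains every fold from that identical initialization.  Each fold's
#' training subset is (optionally) expanded fourfold by [augment_fold()];
#' validation images are never augmented.  Fold weights, per-record CSVs and
#' the summary table are written under `out_dir`.
#'
#' @param samples list of samples `list(image, masks)` at the working
#'   resolution.
#' @param mconfig a [model_config].
#' @param tconfig a [train_config].
#' @param aconfig an [augment_params] (used when `tconfig$augment`).
#' @param out_dir output directory for weights, logs and CSVs (created); if
#'   `NULL`, a temporary directory is used.
#' @return A list with `folds` (list of `fold_result`), `table` (a
#'   [aggregate_metrics()] summary), `init_weights_path` and `out_dir`.
#' @export
cross_validate <- function(samples, mconfig = model_config(),
                           tconfig = train_config(),
                           aconfig = augment_params(), out_dir = NULL) {
  if (is.null(out_dir)) out_dir <- tempfile("cv_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "train.log")
  splits <- kfold_split(length(samples), tconfig)

  model0 <- build_model(mconfig, init_seed = tconfig$init_seed)
  init_path <- file.path(out_dir, "init_weights.rds")
  save_weights(model0, init_path)
  log_line(log_file, sprintf(
    "cross_validate: %d samples, %d folds, seeds split/init/shuffle = %d/%d/%d",
    length(samples), tconfig$k_folds, tconfig$split_seed, tconfig$init_seed,
    tconfig$shuffle_seed))

  folds <- vector("list", length(splits))
  for (f in seq_along(splits)) {
    sp <- splits[[f]]
    train_set <- samples[sp$train]
    if (tconfig$augment) {
      ap <- aconfig
      ap$rng_seed <- as.integer(derive_seed(aconfig$rng_seed, f) %% 2147483646 + 1)
      train_set <- augment_fold(train_set, ap)
    }
    model_f <- load_weights(model0, init_path)   # identical start in every fold
    res <- tryCatch(
      train_fold(model_f, train_set, tconfig, val_samples = samples[sp$val],
                 fold_index = f, log_file = log_file),
      error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                               call. = FALSE))
    save_weights(res$model, file.path(out_dir, sprintf("fold_%d_weights.rds", f)))
    if (!is.null(res$records)) {
      write.csv(res$records, file.path(out_dir, sprintf("fold_%d_records.csv", f)),
                row.names = FALSE)
    }
    folds[[f]] <- res
  }
  tab <- aggregate_metrics(lapply(folds, `[[`, "records"))
  write.csv(as.data.frame(tab), file.path(out_dir, "summary.csv"), row.names = FALSE)
  list(folds = folds, table = tab, init_weights_path = init_path, out_dir = out_dir)
}
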