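#' Scaled-down end-to-end training demonstration
#'
#' Runs the full pipeline at a reduced scale suitable for a single CPU:
#' 30 easy-contrast synthetic images (64 x 64; 5 all-channel cores of radius
#' 12-20 px, peaks 0.9-1.0, background noise sd 0.005, ~25% positive pixels
#' per combination), an 80/20 train/held-out split (24/6), and the
#' four-output network at `base_filters = 8` trained for 10 epochs with
#' Adam 5e-4 and mini-batches of 4.  The reduced run skips offline augmentation; all other
#' protocol elements (shared initialization, shuffling, strict-threshold
#' binarization, per-image metric records) are the full ones.  See the
#' methods vignette for why the easy-contrast regime defines this
#' demonstration.
#'
#' @param seed integer; seeds the generator, initialization, shuffling and
#'   split deterministically.
#' @param epochs,n_samples scale knobs, defaulting to the demonstration
#'   conditions.
#' @return A list: `loss_history` (per-epoch mean training loss), `records`
#'   (held-out per-image-per-output metric data frame), `table`
#'   (aggregated [metrics_table]), `model`, and `held_out` (sample list).
#' @export
scaled_demo_run <- function(seed = 1L, epochs = 10L, n_samples = 30L) {
  sp <- synthetic_params(
    image_size = 64, n_cores = 5, core_radius_range = c(12, 20),
    channel_presence_probs = c(1, 1, 1),
    core_intensity_range = c(0.9, 1.0),
    background_noise_sigma = 0.005, intensity_threshold = 0.5,
    rng_seed = as.integer(derive_seed(seed, 101L))
  )
  samples <- lapply(seq_len(n_samples), function(i) generate_sample(sp, i))
  n_train <- round(0.8 * n_samples)
  perm <- with_seed(derive_seed(seed, 202L), sample.int(n_samples))
  train_idx <- perm[seq_len(n_train)]
  val_idx <- perm[-seq_len(n_train)]

  mcfg <- model_config(input_size = 64, base_filters = 8)
  tcfg <- train_config(
    epochs = epochs, batch_size = 4, learning_rate = 5e-4,
    split_seed = as.integer(derive_seed(seed, 303L) %% 2147483646 + 1),
    init_seed = as.integer(derive_seed(seed, 404L) %% 2147483646 + 1),
    shuffle_seed = as.integer(derive_seed(seed, 505L) %% 2147483646 + 1),
    resize_to = 64, augment = FALSE
  )
  model <- build_model(mcfg, init_seed = tcfg$init_seed)
  res <- train_fold(model, samples[train_idx], tcfg,
                    val_samples = samples[val_idx])
  list(loss_history = res$loss_history, records = res$records,
       table = aggregate_metrics(res$records), model = res$model,
       held_out = samples[val_idx])
}
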