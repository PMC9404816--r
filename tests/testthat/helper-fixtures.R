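# Shared fixtures: everything is generated in code at test time.

# small, easy-contrast generator settings (fast to render, stable masks)
tiny_synth <- function(size = 32, n_cores = 2, seed = 42, noise = 0.02) {
  synthetic_params(
    image_size = size, n_cores = n_cores, core_radius_range = c(3, 7),
    channel_presence_probs = c(0.9, 0.9, 0.9),
    core_intensity_range = c(0.8, 1.0),
    background_noise_sigma = noise, intensity_threshold = 0.5, rng_seed = seed
  )
}

# a small network configuration used by most model/training tests
tiny_model_config <- function(dropout_rate = 0.2, ...) {
  model_config(input_size = 16, input_channels = 3, n_outputs = 4, depth = 3,
               base_filters = 4, kernel_size = 3, dropout_rate = dropout_rate,
               ...)
}

tiny_samples <- function(n, size = 16, seed = 7) {
  sp <- tiny_synth(size = size, seed = seed)
  lapply(seq_len(n), function(i) generate_sample(sp, i))
}

# random binary mask with a given fill probability
random_mask <- function(h, w, p = 0.5) {
  matrix(rbinom(h * w, 1L, p), h, w)
}
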