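# Small, fast phantom used across tests: 96 x 96 matrix, 120 frames at
# 0.3 s (well below the cardiac Nyquist limit for 72 bpm), scaled-down
# vessel tree. Heavier study-scale phantoms are built only where a test
# needs them.
small_config <- function(n_frames = 120, dt = 0.3, matrix = c(96L, 96L)) {
  acquisition_config(n_frames = n_frames, dt = dt, matrix = matrix)
}

small_truth <- function(...) {
  args <- list(...)
  defaults <- list(heart_rate = 72, vessel_area_mean = 140, noise_sd = 0)
  do.call(phantom_truth, utils::modifyList(defaults, args))
}

small_phantom <- function(config = small_config(), ...) {
  generate_phantom(config, small_truth(...))
}
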