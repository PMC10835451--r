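# Shared fixtures: everything is generated in code, nothing is stored.

small_config <- function(n_fast = 64L, n_slow = 16L, ...) {
  system_config(n_fast = n_fast, n_slow = n_slow, ...)
}

# Flat-surface phantom without vessels, relief or layer texture: the
# simplest detectable skin, for exact-position checks.
flat_phantom <- function(depth = 250, amplitude = 1) {
  phantom_spec(
    surface_mean_depth = depth, surface_tilt = c(0, 0),
    surface_undulation = NULL, surface_texture = NULL,
    surface_amplitude = amplitude, vessels = list()
  )
}

# A single point absorber (no surface), for forward-model pinpoint checks.
point_phantom <- function(x, y, z, amplitude = 1) {
  ph <- phantom_spec(
    surface_mean_depth = 1, surface_tilt = c(0, 0),
    surface_undulation = NULL, surface_texture = NULL,
    surface_amplitude = 0, vessels = list()
  )
  ph$vessels <- list(list(center = c(x, y, z), radius = 6, amplitude = amplitude))
  ph
}

# A small full scan used by several suites (memoised per session).
.fixture_cache <- new.env(parent = emptyenv())

cached_scan <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

default_scan_64x16 <- function(noise_std = 0.01, seed = 3L) {
  key <- paste0("scan64x16_", noise_std, "_", seed)
  cached_scan(key, function() {
    simulate_scan(phantom_spec(), small_config(),
      n_samples = 512L,
      noise_std = noise_std, seed = seed
    )
  })
}

sinusoid_graph <- function(n, amplitude, period, dt = 1 / 500) {
  motion_graph_new(amplitude * sin(2 * pi * seq_len(n) / period), dt)
}
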