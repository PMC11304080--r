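# Shared synthetic fixtures, rendered once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, make(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Default beating movie: 3 complete beats at 30 frames/beat, 4 px peak
# deflection, mild sensor noise.
default_movie <- function() {
  fixture("default_movie", function() {
    render_movie(synthetic_movie_spec(peak_amplitude_px = 4,
                                      noise_sigma = 0.02))
  })
}

# Linear-drift movie: 4 complete beats with 0.05 px/frame vertical drift.
drift_movie <- function() {
  fixture("drift_movie", function() {
    render_movie(synthetic_movie_spec(peak_amplitude_px = 4,
                                      noise_sigma = 0.02,
                                      drift_per_frame = c(0.05, 0),
                                      n_frames = 121, texture_seed = 7L))
  })
}

# Noise-free movie for exact-recovery checks.
clean_movie <- function() {
  fixture("clean_movie", function() {
    render_movie(synthetic_movie_spec(peak_amplitude_px = 4,
                                      noise_sigma = 0, texture_seed = 3L))
  })
}

tracked <- function(movie, masks = movie$masks) {
  pillartrack:::track_pillars(movie$stack, masks)
}

# Peak of the mean absolute displacement trace (px), the headline tracking
# quantity.
peak_mean_abs <- function(tracks) {
  max(pillartrack:::pillar_displacement(tracks)$mean_abs)
}

# The five-movie validation set used for the tracking-accuracy and
# mask-sensitivity checks: peak deflections 2-6 px, noise 1-5% of the gray
# range, 3 complete beats each, fixed seeds.
validation_specs <- function(seed_base = 100L) {
  lapply(1:5, function(i) {
    synthetic_movie_spec(peak_amplitude_px = 1 + i,
                         noise_sigma = 0.01 * i,
                         texture_seed = seed_base + i)
  })
}

validation_movies <- function() {
  fixture("validation_movies", function() {
    lapply(validation_specs(), render_movie)
  })
}

get_frame_1 <- function(movie) movie$stack$frames[, , 1]

jaccard <- function(a, b) sum((a > 0) & (b > 0)) / sum((a > 0) | (b > 0))
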