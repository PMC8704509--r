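# Shared fixtures: small geometries, grids, and random complex data.

small_geometry <- function(n_pos = 4, radius = 0.15) {
  circular_scan_geometry(n_pos, radius_m = radius)
}

small_freqs <- function(n = 3, fmin = 1e9, fmax = 9e9) {
  frequency_axis(seq(fmin, fmax, length.out = n))
}

small_grid <- function(n = 10, half = 0.06) {
  image_grid(c(-half, half), c(-half, half), n, n)
}

rand_complex <- function(n, sd = 1) {
  complex(real = rnorm(n, sd = sd), imaginary = rnorm(n, sd = sd))
}

rand_sparams <- function(geometry, freqs, sd = 1) {
  sparameter_set(
    matrix(rand_complex(geometry$n_positions * freqs$n_frequencies, sd),
           geometry$n_positions, freqs$n_frequencies),
    geometry, freqs)
}

rand_profile <- function(grid, sd = 1) {
  reflectivity_profile(matrix(rand_complex(grid$n_pixels, sd),
                              grid$n_y, grid$n_x), grid)
}

# DAS-derived single-measurement closed-form profile (exact zero-loss
# solution): sigma(r) = (1/V) * S * exp(+2*pi*j*f*2 t(r, a)).
sigma_d_profile <- function(s_value, geometry, f_hz, grid, pos_idx = 1) {
  a <- geometry$positions[pos_idx, ]
  tt <- apply(grid$pixel_xy, 1, function(r) time_delay(r, a, geometry$speed))
  vals <- (1 / grid$domain_area) * s_value * exp(2i * pi * f_hz * 2 * tt)
  reflectivity_profile(matrix(vals, grid$n_y, grid$n_x), grid)
}
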