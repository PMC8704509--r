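# Radar forward scattering models.
#
# First-order (Born-style) model: the measured S-parameter is the
# area-weighted sum of pixel reflectivities, each delayed by the monostatic
# round trip,
#
#   S_fwd(a, f) = dA * sum_r sigma(r) * exp(-2*pi*j * f * 2 t(r, a)).
#
# The integral over the imaging domain is discretized by the midpoint rule
# over pixel centres with weight dA (the pixel area), which makes the
# single-measurement closed-form solution exact on the grid.

# Phase matrix flattened to measurements x pixels, measurement index
# k = (freq_idx - 1) * n_positions + pos_idx — i.e. position fastest,
# matching as.vector() of an (n_positions x n_frequencies) value matrix.
.forward_phase <- function(grid, geometry, freqs) {
  tau2 <- .delay2_matrix(geometry, grid)
  exp(-2i * pi * kronecker(matrix(freqs$frequencies, ncol = 1), tau2))
}

# Bytes needed for the flattened phase matrix.
.phase_bytes <- function(grid, geometry, freqs) {
  16 * as.numeric(geometry$n_positions) * freqs$n_frequencies * grid$n_pixels
}

#' Precomputed round-trip phase factors
#'
#' The phasor `exp(-2*pi*j * f * 2 t(r, a))` shared by the forward model and
#' both beamformers, tabulated for every (antenna position, frequency, pixel)
#' triple. Every entry has unit modulus. Intended for repeated reconstructions
#' on a fixed geometry; the streaming code paths recompute the same factors
#' per frequency without materializing this array.
#'
#' @param grid An [image_grid()].
#' @param geometry A [scan_geometry()].
#' @param freqs A [frequency_axis()].
#' @param max_bytes Memory budget in bytes (default 512 MiB). If the requested
#'   array would exceed it, the call fails with a message directing callers to
#'   the streaming path.
#' @return A complex array of dimension
#'   `(n_positions, n_frequencies, n_pixels)`; pixel index `p` corresponds to
#'   `as.vector()` of an `(n_y, n_x)` value matrix.
#' @export
phase_matrix <- function(grid, geometry, freqs, max_bytes = 512 * 1024^2) {
  .assert(inherits(grid, "image_grid") && inherits(geometry, "scan_geometry") &&
            inherits(freqs, "frequency_axis"), "invalid input types")
  need <- .phase_bytes(grid, geometry, freqs)
  if (need > max_bytes) {
    stop(sprintf(paste0(
      "phase_matrix would need %.2f MiB (> budget %.2f MiB); ",
      "use the streaming forward/beamformer paths instead of precomputation"),
      need / 1024^2, max_bytes / 1024^2), call. = FALSE)
  }
  tau2 <- .delay2_matrix(geometry, grid) # n_pos x n_pix
  out <- array(0 + 0i, dim = c(geometry$n_positions, freqs$n_frequencies,
                               grid$n_pixels))
  for (k in seq_len(freqs$n_frequencies)) {
    out[, k, ] <- exp(-2i * pi * freqs$frequencies[k] * tau2)
  }
  out
}

#' First-order radar forward model
#'
#' Maps a reflectivity profile to the S-parameters it would produce under the
#' linear single-scattering model implicit in delay-and-sum imaging (see the
#' package vignette). Linear in the profile.
#'
#' @param profile A [reflectivity_profile()].
#' @param geometry A [scan_geometry()].
#' @param freqs A [frequency_axis()].
#' @param phase Optional flattened phase matrix from the internal layout
#'   (`(n_positions * n_frequencies) x n_pixels`); when supplied, reused
#'   instead of recomputing phases (advanced use; must match the inputs).
#' @return A [sparameter_set()] of forward-model S-parameters.
#' @export
forward_model <- function(profile, geometry, freqs, phase = NULL) {
  .assert(inherits(profile, "reflectivity_profile"),
          "profile must be a reflectivity_profile")
  .assert(inherits(geometry, "scan_geometry") &&
            inherits(freqs, "frequency_axis"), "invalid geometry/frequency input")
  grid <- profile$grid
  sig <- as.vector(profile$values)
  dA <- grid$pixel_area
  n_pos <- geometry$n_positions
  n_f <- freqs$n_frequencies
  if (!is.null(phase)) {
    .assert(all(dim(phase) == c(n_pos * n_f, grid$n_pixels)),
            "phase matrix shape mismatch")
    s <- matrix(dA * (phase %*% sig), nrow = n_pos, ncol = n_f)
  } else {
    # stream per frequency: no n_meas x n_pixels allocation
    tau2 <- .delay2_matrix(geometry, grid)
    s <- matrix(0 + 0i, n_pos, n_f)
    for (k in seq_len(n_f)) {
      s[, k] <- dA * (exp(-2i * pi * freqs$frequencies[k] * tau2) %*% sig)
    }
  }
  sparameter_set(s, geometry, freqs)
}

#' Second-order scattering forward model
#'
#' Augments the first-order model with double-scattering paths
#' antenna -> r' -> r -> antenna: the second term integrates, over pixel
#' pairs, `sigma(r) sigma(r') exp(-2*pi*j*f*[t(r',a) + t(r,r') + t(r,a)])`,
#' discretized with one factor of the pixel area per integral. Reduces to
#' [forward_model()] when the second-order term vanishes. Cost grows with the
#' square of the pixel count, so a size guard refuses oversized grids.
#'
#' @inheritParams forward_model
#' @param max_pixels Refuse grids with more pixels than this (quadratic cost
#'   guard); the error message suggests a workable grid size.
#' @return A [sparameter_set()].
#' @export
forward_model_second_order <- function(profile, geometry, freqs,
                                       max_pixels = 4096) {
  .assert(inherits(profile, "reflectivity_profile"),
          "profile must be a reflectivity_profile")
  grid <- profile$grid
  if (grid$n_pixels > max_pixels) {
    stop(sprintf(paste0(
      "second-order forward model scales with n_pixels^2; grid has %d pixels ",
      "(guard: %d). Use a coarser grid (e.g. <= %d x %d) or raise max_pixels."),
      grid$n_pixels, max_pixels, floor(sqrt(max_pixels)), floor(sqrt(max_pixels))),
      call. = FALSE)
  }
  s <- .simulate_profiles(matrix(as.vector(profile$values), ncol = 1),
                          geometry, freqs, grid, order = 2)[, , 1]
  sparameter_set(matrix(s, geometry$n_positions, freqs$n_frequencies),
                 geometry, freqs)
}

# Batched forward simulation of several reflectivity profiles sharing one
# (grid, geometry, frequency axis). sigma_mat: n_pixels x n_profiles complex.
# Returns array (n_positions, n_frequencies, n_profiles).
# order = 1: linear model. order = 2: adds the double-scattering term.
# The per-frequency pixel-pair phase matrix is built once per frequency and
# shared across profiles and antenna positions, which keeps the quadratic
# cost manageable for cohort generation.
.simulate_profiles <- function(sigma_mat, geometry, freqs, grid, order = 1) {
  .assert(order %in% c(1, 2), "order must be 1 or 2")
  n_pos <- geometry$n_positions
  n_f <- freqs$n_frequencies
  n_prof <- ncol(sigma_mat)
  n_pix <- grid$n_pixels
  .assert(nrow(sigma_mat) == n_pix, "profile length mismatch with grid")
  dA <- grid$pixel_area
  t1 <- .pos_pixel_dist(geometry, grid) / geometry$speed # one-way, n_pos x n_pix
  out <- array(0 + 0i, dim = c(n_pos, n_f, n_prof))
  if (order == 2) {
    px <- grid$pixel_xy
    dpp <- sqrt(outer(px[, 1], px[, 1], "-")^2 + outer(px[, 2], px[, 2], "-")^2)
    tpp <- dpp / geometry$speed # pixel-pair one-way delays
  }
  for (k in seq_len(n_f)) {
    f <- freqs$frequencies[k]
    e1 <- exp(-2i * pi * f * t1)      # one-way phasor, n_pos x n_pix
    e2 <- e1 * e1                     # round-trip phasor
    out[, k, ] <- dA * (e2 %*% sigma_mat)
    if (order == 2) {
      kf <- exp(-2i * pi * f * tpp)   # n_pix x n_pix
      te1 <- t(e1)                    # n_pix x n_pos
      for (p in seq_len(n_prof)) {
        u <- sigma_mat[, p] * te1     # u[r, a] = sigma(r) e^{-2pi j f t(r,a)}
        w <- kf %*% u
        out[, k, p] <- out[, k, p] + dA * dA * colSums(u * w)
      }
    }
  }
  out
}
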