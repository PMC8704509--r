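# One-step beamformers: delay-and-sum (DAS) and delay-multiply-and-sum (DMAS).
#
# Both beamformers align the measured S-parameters to each candidate pixel by
# multiplying with the phase-compensating conjugate of the forward-model
# round-trip phasor, exp(+2*pi*j * f * 2 t(r, a)), then sum coherently. With
# this convention DAS is exactly the adjoint of the first-order forward model
# (up to the pixel-area quadrature weight), which ties the one-step
# reconstruction to the gradient of the least-squares data-fit loss; see the
# methods vignette for the phase-sign discussion.

#' Reconstructed image container
#'
#' @param intensity Complex `(n_y, n_x)` matrix of image values; the
#'   displayed image is the magnitude `Mod(intensity)`.
#' @param grid The [image_grid()] the image lives on.
#' @param algorithm One of `"DAS"`, `"DMAS"`, `"ORR"`.
#' @return An object of class `reconstructed_image`.
#' @export
reconstructed_image <- function(intensity, grid, algorithm) {
  .assert(inherits(grid, "image_grid"), "grid must be an image_grid")
  .assert(algorithm %in% c("DAS", "DMAS", "ORR"),
          "algorithm must be one of DAS, DMAS, ORR")
  intensity <- as.matrix(intensity)
  .assert(all(dim(intensity) == c(grid$n_y, grid$n_x)),
          "image shape must match the grid")
  storage.mode(intensity) <- "complex"
  .assert(all(is.finite(Re(intensity))) && all(is.finite(Im(intensity))),
          "image values must be finite")
  structure(list(intensity = intensity, grid = grid, algorithm = algorithm),
            class = "reconstructed_image")
}

#' @export
print.reconstructed_image <- function(x, ...) {
  cat(sprintf("<reconstructed_image> %s, %d x %d, max |I| = %.4g\n",
              x$algorithm, x$grid$n_y, x$grid$n_x, max(Mod(x$intensity))))
  invisible(x)
}

#' Image magnitude
#' @param image A [reconstructed_image()].
#' @param normalize Divide by the maximum magnitude (when nonzero).
#' @return Numeric `(n_y, n_x)` matrix of `|I|`.
#' @export
image_magnitude <- function(image, normalize = FALSE) {
  m <- Mod(image$intensity)
  if (normalize && max(m) > 0) m <- m / max(m)
  m
}

#' Delay-and-sum (DAS) beamformer
#'
#' Coherently sums all measurements after compensating each for the
#' round-trip phase to the candidate pixel:
#' `I(r) = sum_a sum_f S(a, f) * exp(+2*pi*j*f*2 t(r, a))`.
#' This is the adjoint of [forward_model()] applied to the data (up to the
#' pixel-area weight dA): for a single-position, single-frequency
#' measurement, `I(r) / V` is the exact zero-loss solution of the
#' least-squares problem, where `V` is the domain area.
#'
#' @param data A [sparameter_set()] (must contain at least one measurement).
#' @param grid The [image_grid()] to reconstruct on.
#' @return A [reconstructed_image()] with `algorithm = "DAS"`.
#' @export
das <- function(data, grid) {
  .assert(inherits(data, "sparameter_set"), "data must be a sparameter_set")
  .assert(inherits(grid, "image_grid"), "grid must be an image_grid")
  .assert(length(data$values) >= 1, "empty S-parameter data")
  geometry <- data$geometry
  freqs <- data$frequency_axis
  tau2 <- .delay2_matrix(geometry, grid)
  ivec <- rep(0 + 0i, grid$n_pixels)
  for (k in seq_len(freqs$n_frequencies)) {
    # column-wise recycling of S[, k] down each pixel column
    ivec <- ivec + colSums(exp(2i * pi * freqs$frequencies[k] * tau2) *
                             data$values[, k])
  }
  reconstructed_image(matrix(ivec, grid$n_y, grid$n_x), grid, "DAS")
}

#' Delay-multiply-and-sum (DMAS) beamformer
#'
#' Multiplies delay-compensated signal pairs from distinct antenna positions
#' before summation. With `x_af(r) = S(a, f) * exp(+2*pi*j*f*2 t(r, a))`, the
#' image is the cross-product sum over position pairs `a != a'` at each
#' frequency, computed via the closed form
#' `I(r) = sum_f [ (sum_a x_af)^2 - sum_a x_af^2 ]`
#' which excludes the autoproduct (`a == a'`) terms exactly.
#'
#' @inheritParams das
#' @return A [reconstructed_image()] with `algorithm = "DMAS"`.
#' @export
dmas <- function(data, grid) {
  .assert(inherits(data, "sparameter_set"), "data must be a sparameter_set")
  .assert(inherits(grid, "image_grid"), "grid must be an image_grid")
  if (data$geometry$n_positions < 2) {
    stop(paste("DMAS requires at least two antenna positions: the autoproduct",
               "terms (a == a') are excluded, so a single-position sum is",
               "identically zero"), call. = FALSE)
  }
  geometry <- data$geometry
  freqs <- data$frequency_axis
  tau2 <- .delay2_matrix(geometry, grid)
  ivec <- rep(0 + 0i, grid$n_pixels)
  for (k in seq_len(freqs$n_frequencies)) {
    x <- exp(2i * pi * freqs$frequencies[k] * tau2) * data$values[, k]
    s1 <- colSums(x)
    s2 <- colSums(x * x)
    ivec <- ivec + (s1 * s1 - s2)
  }
  reconstructed_image(matrix(ivec, grid$n_y, grid$n_x), grid, "DMAS")
}
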