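# Imaging grid and reflectivity-profile containers.

#' Cartesian imaging grid
#'
#' Regular 2D pixel lattice over the imaging domain. Pixel values throughout
#' the package are stored as `(n_y, n_x)` matrices with row `i` corresponding
#' to the i-th y coordinate (ascending) and column `j` to the j-th x
#' coordinate (ascending). Pixel centres follow the midpoint rule, so the
#' quadrature weight of every pixel is the pixel area `dx * dy` and the total
#' domain area is `n_x * n_y * pixel_area`.
#'
#' @param x_range,y_range Length-2 numeric extents in metres.
#' @param n_x,n_y Pixel counts along x and y (>= 1).
#' @param roi_centre,roi_radius Optional circular region-of-interest: when
#'   `roi_radius` is given, a logical `(n_y, n_x)` mask of pixels whose
#'   centres fall inside the circle is stored as `roi`.
#' @return An object of class `image_grid` with pixel centres (`x`, `y`,
#'   `pixel_xy`), spacings (`dx`, `dy`), `pixel_area`, `domain_area`,
#'   `n_pixels`, and optional `roi` mask.
#' @examples
#' g <- image_grid(c(-0.08, 0.08), c(-0.08, 0.08), 40, 40)
#' g$pixel_area
#' @export
image_grid <- function(x_range = c(-0.08, 0.08), y_range = c(-0.08, 0.08),
                       n_x = 40, n_y = 40,
                       roi_centre = c(0, 0), roi_radius = NULL) {
  .assert(length(x_range) == 2 && length(y_range) == 2 &&
            all(is.finite(c(x_range, y_range))),
          "x_range and y_range must be finite length-2 extents (metres)")
  .assert(diff(x_range) > 0 && diff(y_range) > 0,
          "grid extents must have positive width")
  .assert(n_x >= 1 && n_y >= 1, "pixel counts must be >= 1")
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  dx <- diff(x_range) / n_x
  dy <- diff(y_range) / n_y
  x <- x_range[1] + dx * (seq_len(n_x) - 0.5)
  y <- y_range[1] + dy * (seq_len(n_y) - 0.5)
  # pixel index p = (ix - 1) * n_y + iy matches as.vector() of an
  # (n_y, n_x) value matrix (column-major).
  pixel_xy <- cbind(rep(x, each = n_y), rep(y, times = n_x))
  roi <- NULL
  if (!is.null(roi_radius)) {
    .assert(is.numeric(roi_radius) && roi_radius > 0,
            "roi_radius must be positive")
    d2 <- (pixel_xy[, 1] - roi_centre[1])^2 + (pixel_xy[, 2] - roi_centre[2])^2
    roi <- matrix(d2 <= roi_radius^2, nrow = n_y, ncol = n_x)
  }
  structure(
    list(x_range = as.numeric(x_range), y_range = as.numeric(y_range),
         n_x = n_x, n_y = n_y, x = x, y = y, dx = dx, dy = dy,
         pixel_area = dx * dy, domain_area = n_x * n_y * dx * dy,
         n_pixels = n_x * n_y, pixel_xy = pixel_xy, roi = roi),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf(
    "<image_grid> %d x %d pixels over [%.3g, %.3g] x [%.3g, %.3g] m (dA = %.3g m^2)\n",
    x$n_x, x$n_y, x$x_range[1], x$x_range[2], x$y_range[1], x$y_range[2],
    x$pixel_area))
  invisible(x)
}

#' Complex reflectivity profile on an imaging grid
#'
#' The reconstruction unknown: a complex scattering-strength map sampled at
#' the pixel centres of an [image_grid()]. Used both as the ground truth of
#' the simulator and as the iterate of the optimization-based reconstruction.
#'
#' @param values Complex (or numeric) `(n_y, n_x)` matrix; must match the grid
#'   and be finite.
#' @param grid An [image_grid()].
#' @return An object of class `reflectivity_profile`.
#' @export
reflectivity_profile <- function(values, grid) {
  .assert(inherits(grid, "image_grid"), "grid must be an image_grid")
  values <- as.matrix(values)
  .assert(all(dim(values) == c(grid$n_y, grid$n_x)),
          sprintf("profile values must be a %d x %d matrix matching the grid",
                  grid$n_y, grid$n_x))
  storage.mode(values) <- "complex"
  .assert(all(is.finite(Re(values))) && all(is.finite(Im(values))),
          "profile values must be finite")
  structure(list(values = values, grid = grid), class = "reflectivity_profile")
}

#' Zero reflectivity profile
#' @param grid An [image_grid()].
#' @return A `reflectivity_profile` of zeros.
#' @export
zero_profile <- function(grid) {
  reflectivity_profile(matrix(0 + 0i, grid$n_y, grid$n_x), grid)
}

#' @export
print.reflectivity_profile <- function(x, ...) {
  cat(sprintf("<reflectivity_profile> %d x %d complex, max |sigma| = %.4g\n",
              x$grid$n_y, x$grid$n_x, max(Mod(x$values))))
  invisible(x)
}
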