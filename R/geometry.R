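# Scan geometry, frequency axis, and time-of-flight primitives.
#
# Coordinate convention (used package-wide): origin at the centre of the
# imaging chamber, units of metres, antenna angles measured counter-clockwise
# from the +x axis. All propagation is monostatic: the antenna at position `a`
# both transmits and receives, so image-formation phases carry the round-trip
# factor 2 t(r, a).

.c0 <- 299792458 # vacuum speed of light, m/s

.assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

#' Monostatic scan geometry
#'
#' Bundles the antenna positions of a monostatic scan with the (homogeneous)
#' propagation speed assumed for time-of-flight computations. The speed can be
#' given directly or derived from an average relative permittivity of the
#' imaging domain as `v = c0 / sqrt(avg_permittivity)`.
#'
#' @param antenna_positions Numeric matrix with one row per antenna position
#'   and two columns (x, y), in metres.
#' @param speed Propagation speed in m/s. If `NULL`, derived from
#'   `avg_permittivity`.
#' @param avg_permittivity Average relative permittivity of the propagation
#'   path, used only when `speed` is `NULL`. The default of 3 reflects a path
#'   that is mostly air with a partial traversal of low-water-content tissue.
#' @return An object of class `scan_geometry` with elements `positions`,
#'   `speed`, `n_positions`.
#' @seealso [circular_scan_geometry()] for the standard circular-arc
#'   constructor.
#' @export
scan_geometry <- function(antenna_positions, speed = NULL,
                          avg_permittivity = 3.0) {
  antenna_positions <- as.matrix(antenna_positions)
  .assert(is.numeric(antenna_positions) && ncol(antenna_positions) == 2,
          "antenna_positions must be an n x 2 numeric matrix of (x, y) metres")
  .assert(nrow(antenna_positions) >= 1, "at least one antenna position is required")
  .assert(all(is.finite(antenna_positions)), "antenna positions must be finite")
  if (is.null(speed)) {
    .assert(is.numeric(avg_permittivity) && length(avg_permittivity) == 1 &&
              is.finite(avg_permittivity) && avg_permittivity > 0,
            "avg_permittivity must be a positive finite scalar")
    speed <- .c0 / sqrt(avg_permittivity)
  }
  .assert(is.numeric(speed) && length(speed) == 1 && is.finite(speed) &&
            speed > 0, "propagation speed must be a positive finite scalar")
  structure(
    list(positions = unname(antenna_positions), speed = as.numeric(speed),
         n_positions = nrow(antenna_positions)),
    class = "scan_geometry"
  )
}

#' Circular-arc monostatic scan geometry
#'
#' Places `n_positions` antenna positions equally spaced in angle along a
#' circular arc of the given radius and angular span, mirroring rotating-arm
#' BMS scan protocols (e.g. 72 positions spanning 355 degrees).
#'
#' @param n_positions Number of antenna positions (>= 1).
#' @param radius_m Arc radius in metres (antenna distance from the chamber
#'   centre).
#' @param arc_span_deg Angular span of the arc in degrees; positions sit at
#'   `seq(start, start + span, length.out = n_positions)`.
#' @param start_angle_deg Angle of the first position, degrees CCW from +x.
#' @inheritParams scan_geometry
#' @return A `scan_geometry`.
#' @examples
#' g <- circular_scan_geometry(8, radius_m = 0.15)
#' g$n_positions
#' @export
circular_scan_geometry <- function(n_positions = 72, radius_m = 0.15,
                                   arc_span_deg = 355, start_angle_deg = 0,
                                   speed = NULL, avg_permittivity = 3.0) {
  .assert(is.numeric(n_positions) && n_positions >= 1,
          "n_positions must be >= 1")
  .assert(is.numeric(radius_m) && radius_m > 0, "radius_m must be positive")
  n_positions <- as.integer(n_positions)
  if (n_positions == 1L) {
    ang <- start_angle_deg
  } else {
    ang <- seq(start_angle_deg, start_angle_deg + arc_span_deg,
               length.out = n_positions)
  }
  ang <- ang * pi / 180
  pos <- cbind(radius_m * cos(ang), radius_m * sin(ang))
  g <- scan_geometry(pos, speed = speed, avg_permittivity = avg_permittivity)
  g$radius_m <- radius_m
  g$arc_span_deg <- arc_span_deg
  g
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %d monostatic positions, v = %.4g m/s\n",
              x$n_positions, x$speed))
  invisible(x)
}

#' Frequency axis of a stepped-frequency scan
#'
#' @param frequencies Numeric vector of frequencies in hertz; strictly
#'   increasing, finite and non-negative.
#' @return An object of class `frequency_axis` with elements `frequencies`
#'   and `n_frequencies`.
#' @examples
#' fa <- frequency_axis(seq(1e9, 9e9, length.out = 11))
#' @export
frequency_axis <- function(frequencies) {
  frequencies <- as.numeric(frequencies)
  .assert(length(frequencies) >= 1, "at least one frequency is required")
  .assert(all(is.finite(frequencies)) && all(frequencies >= 0),
          "frequencies must be finite and non-negative (hertz)")
  .assert(length(frequencies) == 1 || all(diff(frequencies) > 0),
          "frequencies must be strictly increasing")
  structure(list(frequencies = frequencies,
                 n_frequencies = length(frequencies)),
            class = "frequency_axis")
}

#' @export
print.frequency_axis <- function(x, ...) {
  cat(sprintf("<frequency_axis> %d frequencies, %.3g-%.3g Hz\n",
              x$n_frequencies, min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' One-way propagation time delay
#'
#' Straight-ray time of flight `|r - a| / v` between two points under a
#' homogeneous propagation speed. Monostatic image-formation phases use twice
#' this value (round trip).
#'
#' @param r,a Numeric length-2 points (x, y) in metres.
#' @param v Propagation speed, m/s (> 0).
#' @return Delay in seconds (non-negative; symmetric in `r` and `a`).
#' @examples
#' time_delay(c(0.03, 0.04), c(0, 0), 2e8) # 2.5e-10 s
#' @export
time_delay <- function(r, a, v) {
  .assert(is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0,
          "propagation speed v must be a positive finite scalar")
  .assert(length(r) == 2 && length(a) == 2 && all(is.finite(c(r, a))),
          "r and a must be finite length-2 points")
  sqrt(sum((r - a)^2)) / v
}

# Euclidean distances between antenna positions and pixel centres.
# Returns an (n_positions x n_pixels) matrix.
.pos_pixel_dist <- function(geometry, grid) {
  px <- grid$pixel_xy
  dx <- outer(geometry$positions[, 1], px[, 1], "-")
  dy <- outer(geometry$positions[, 2], px[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

# Round-trip (two-way) delays, seconds: (n_positions x n_pixels).
.delay2_matrix <- function(geometry, grid) {
  2 * .pos_pixel_dist(geometry, grid) / geometry$speed
}
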