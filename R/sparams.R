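# S-parameter containers and reference-scan subtraction.

#' Monostatic S-parameter set
#'
#' Complex S11 measurements on a (antenna position x frequency) lattice,
#' together with the scan geometry and frequency axis that index them.
#'
#' @param values Complex `(n_positions, n_frequencies)` matrix.
#' @param geometry A [scan_geometry()].
#' @param frequency_axis A [frequency_axis()].
#' @return An object of class `sparameter_set`.
#' @export
sparameter_set <- function(values, geometry, frequency_axis) {
  .assert(inherits(geometry, "scan_geometry"), "geometry must be a scan_geometry")
  .assert(inherits(frequency_axis, "frequency_axis"),
          "frequency_axis must be a frequency_axis")
  values <- as.matrix(values)
  .assert(all(dim(values) == c(geometry$n_positions,
                               frequency_axis$n_frequencies)),
          sprintf("S-parameter values must be %d x %d (positions x frequencies)",
                  geometry$n_positions, frequency_axis$n_frequencies))
  storage.mode(values) <- "complex"
  .assert(all(is.finite(Re(values))) && all(is.finite(Im(values))),
          "S-parameter values must be finite")
  structure(list(values = values, geometry = geometry,
                 frequency_axis = frequency_axis),
            class = "sparameter_set")
}

#' @export
print.sparameter_set <- function(x, ...) {
  cat(sprintf("<sparameter_set> %d positions x %d frequencies, max |S| = %.4g\n",
              x$geometry$n_positions, x$frequency_axis$n_frequencies,
              max(Mod(x$values))))
  invisible(x)
}

# Check that two sparameter_sets share axes (geometry + frequencies).
.same_axes <- function(a, b, tol = 1e-12) {
  isTRUE(all.equal(a$geometry$positions, b$geometry$positions, tolerance = tol)) &&
    isTRUE(all.equal(a$geometry$speed, b$geometry$speed, tolerance = tol)) &&
    isTRUE(all.equal(a$frequency_axis$frequencies, b$frequency_axis$frequencies,
                     tolerance = tol))
}

#' Subtract a reference scan
#'
#' Element-wise complex difference `target - reference`. Reference-scan
#' subtraction suppresses responses shared by both scans — most importantly
#' the dominant air–tissue interface reflection (using an adipose-only
#' reference) or all non-tumour responses (using a healthy reference).
#'
#' @param target,reference [sparameter_set()]s on identical geometry and
#'   frequency axes.
#' @return A [sparameter_set()] of the difference.
#' @export
subtract_reference <- function(target, reference) {
  .assert(inherits(target, "sparameter_set") &&
            inherits(reference, "sparameter_set"),
          "target and reference must be sparameter_sets")
  .assert(.same_axes(target, reference),
          "target and reference must share identical geometry and frequency axes")
  sparameter_set(target$values - reference$values, target$geometry,
                 target$frequency_axis)
}
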