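# Synthetic scan generator.
#
# Emulates the structure of an open-access monostatic BMS phantom dataset:
# circular-arc scans of layered phantoms (adipose disc + fibroglandular
# inclusions + optional tumour), each tumour scan accompanied by a healthy
# reference (same phantom without the tumour), an adipose reference (breast
# disc only) and an empty-chamber reference. Reflectivity amplitudes are
# free parameters of the emulation; the defaults put the tumour above the
# fibroglandular and adipose tissue (reflectivity contrast) and set the
# overall scale so that second-order scattering contributes an appreciable
# (~10%) fraction of the reference-subtracted signal, mimicking the model
# mismatch a linear reconstruction faces on real measurements.

# run `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Layered phantom specification
#'
#' Geometric description of a synthetic breast phantom: an adipose (breast)
#' disc, zero or more fibroglandular discs inside it, and an optional tumour
#' disc. Amplitudes may be complex.
#'
#' @param breast_centre Length-2 centre of the breast disc, metres.
#' @param breast_radius Breast disc radius, metres.
#' @param breast_amplitude Reflectivity amplitude of adipose tissue.
#' @param fibro `NULL` or a list of components, each a list with `centre`,
#'   `radius`, `amplitude`.
#' @param tumour `NULL` or a list with `centre`, `radius`, `amplitude`; the
#'   tumour must lie entirely inside the breast disc.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(breast_centre = c(0, 0), breast_radius = 0.055,
                         breast_amplitude = 10,
                         fibro = NULL, tumour = NULL) {
  .assert(length(breast_centre) == 2 && all(is.finite(breast_centre)),
          "breast_centre must be a finite length-2 point")
  .assert(is.numeric(breast_radius) && breast_radius > 0,
          "breast_radius must be positive")
  .assert(is.finite(Re(breast_amplitude)) && is.finite(Im(complex(real = 0) + breast_amplitude)),
          "breast_amplitude must be finite")
  check_disc <- function(d, what) {
    .assert(is.list(d) && all(c("centre", "radius", "amplitude") %in% names(d)),
            sprintf("%s must be a list with centre, radius, amplitude", what))
    .assert(length(d$centre) == 2 && all(is.finite(d$centre)) && d$radius > 0,
            sprintf("%s geometry invalid", what))
  }
  if (!is.null(fibro)) {
    .assert(is.list(fibro), "fibro must be a list of components")
    for (fb in fibro) check_disc(fb, "fibroglandular component")
  }
  if (!is.null(tumour)) {
    check_disc(tumour, "tumour")
    inside <- sqrt(sum((tumour$centre - breast_centre)^2)) + tumour$radius <=
      breast_radius
    .assert(inside, "tumour must lie entirely inside the breast disc")
  }
  structure(list(breast_centre = as.numeric(breast_centre),
                 breast_radius = as.numeric(breast_radius),
                 breast_amplitude = breast_amplitude,
                 fibro = fibro, tumour = tumour),
            class = "phantom_spec")
}

#' Rasterize a phantom onto an imaging grid
#'
#' Pixel value = sum of the amplitudes of all tissue shapes whose disc covers
#' the pixel centre, except that the tumour amplitude *replaces* the
#' underlying tissue value where the tumour is present. Deterministic.
#'
#' @param spec A [phantom_spec()].
#' @param grid An [image_grid()].
#' @param include Which components to rasterize: `"all"` (default),
#'   `"healthy"` (drop the tumour), `"adipose"` (breast disc only),
#'   `"tumour_only"` (tumour disc alone, on an empty background).
#' @return A [reflectivity_profile()].
#' @export
rasterize_phantom <- function(spec, grid,
                              include = c("all", "healthy", "adipose",
                                          "tumour_only")) {
  .assert(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  .assert(inherits(grid, "image_grid"), "grid must be an image_grid")
  include <- match.arg(include)
  vals <- matrix(0 + 0i, grid$n_y, grid$n_x)
  in_disc <- function(centre, radius) .pixel_dist(grid, centre) <= radius
  if (include != "tumour_only") {
    vals[in_disc(spec$breast_centre, spec$breast_radius)] <-
      spec$breast_amplitude
    if (include != "adipose" && !is.null(spec$fibro)) {
      for (fb in spec$fibro) {
        m <- in_disc(fb$centre, fb$radius)
        vals[m] <- vals[m] + fb$amplitude
      }
    }
  }
  if (include %in% c("all", "tumour_only") && !is.null(spec$tumour)) {
    vals[in_disc(spec$tumour$centre, spec$tumour$radius)] <-
      spec$tumour$amplitude # replaces underlying tissue
  }
  reflectivity_profile(vals, grid)
}

# metadata for a spec (nominal tumour geometry even for healthy records)
.spec_metadata <- function(spec, has_tumour, nominal_tumour = NULL,
                           positioning_uncertainty = 0.004) {
  tum <- if (!is.null(spec$tumour)) spec$tumour else nominal_tumour
  .assert(!is.null(tum),
          "a (nominal) tumour geometry is required to build phantom metadata")
  phantom_metadata(has_tumour = has_tumour, tumour_centre = tum$centre,
                   tumour_radius = tum$radius,
                   positioning_uncertainty = positioning_uncertainty,
                   breast_boundary_radius = spec$breast_radius,
                   breast_centre = spec$breast_centre)
}

#' Simulate one scan record (target + reference triplet)
#'
#' Produces the four S-parameter sets of one scan: the target scan of the
#' full phantom, a healthy reference (tumour removed), an adipose reference
#' (breast disc only) and an empty-chamber reference, each with independent
#' complex circular Gaussian noise of standard deviation `noise_sigma` per
#' real/imaginary component. Identical seeds give bit-identical records.
#'
#' @param spec A [phantom_spec()].
#' @param geometry A [scan_geometry()].
#' @param freqs A [frequency_axis()].
#' @param grid An [image_grid()] on which the ground truth is rasterized.
#' @param noise_sigma Noise standard deviation per real/imaginary component
#'   (default 0: noiseless).
#' @param order Forward-model order: 1 (linear) or 2 (adds double
#'   scattering; quadratic cost, guarded by `max_pixels`).
#' @param seed Integer RNG seed for the noise draws (required).
#' @param id Scan identifier string.
#' @param nominal_tumour For tumour-free specs, the paired nominal tumour
#'   geometry (list with `centre`, `radius`) recorded in the metadata.
#' @param positioning_uncertainty Metadata delta_r, metres.
#' @param max_pixels Pixel-count guard for `order = 2`.
#' @return An object of class `scan_record`: `id`, `target`, `healthy_ref`,
#'   `adipose_ref`, `empty_ref` ([sparameter_set()]s sharing axes),
#'   `metadata` ([phantom_metadata()]), `spec`, `seed`.
#' @export
simulate_scan <- function(spec, geometry, freqs, grid, noise_sigma = 0,
                          order = 1, seed, id = "scan",
                          nominal_tumour = NULL,
                          positioning_uncertainty = 0.004,
                          max_pixels = 4096) {
  .assert(!missing(seed), "an explicit seed is required")
  .assert(is.numeric(noise_sigma) && noise_sigma >= 0,
          "noise_sigma must be non-negative")
  .assert(order %in% c(1, 2), "order must be 1 or 2")
  if (order == 2 && grid$n_pixels > max_pixels) {
    stop(sprintf(paste0(
      "order-2 simulation scales with n_pixels^2; grid has %d pixels ",
      "(guard: %d) — use a coarser grid"), grid$n_pixels, max_pixels),
      call. = FALSE)
  }
  profiles <- cbind(
    as.vector(rasterize_phantom(spec, grid, "all")$values),
    as.vector(rasterize_phantom(spec, grid, "healthy")$values),
    as.vector(rasterize_phantom(spec, grid, "adipose")$values)
  )
  s <- .simulate_profiles(profiles, geometry, freqs, grid, order = order)
  n_pos <- geometry$n_positions
  n_f <- freqs$n_frequencies
  noise <- .with_seed(seed, {
    lapply(1:4, function(i) {
      if (noise_sigma == 0) {
        matrix(0 + 0i, n_pos, n_f)
      } else {
        matrix(complex(real = stats::rnorm(n_pos * n_f, sd = noise_sigma),
                       imaginary = stats::rnorm(n_pos * n_f, sd = noise_sigma)),
               n_pos, n_f)
      }
    })
  })
  mk <- function(vals, nz) sparameter_set(vals + nz, geometry, freqs)
  structure(list(
    id = id,
    target = mk(matrix(s[, , 1], n_pos, n_f), noise[[1]]),
    healthy_ref = mk(matrix(s[, , 2], n_pos, n_f), noise[[2]]),
    adipose_ref = mk(matrix(s[, , 3], n_pos, n_f), noise[[3]]),
    empty_ref = mk(matrix(0 + 0i, n_pos, n_f), noise[[4]]),
    metadata = .spec_metadata(spec, has_tumour = !is.null(spec$tumour),
                              nominal_tumour = nominal_tumour,
                              positioning_uncertainty = positioning_uncertainty),
    spec = spec, seed = as.integer(seed)
  ), class = "scan_record")
}

#' @export
print.scan_record <- function(x, ...) {
  cat(sprintf("<scan_record> %s (%s), %d positions x %d frequencies, seed %d\n",
              x$id, if (x$metadata$has_tumour) "tumour" else "healthy",
              x$target$geometry$n_positions,
              x$target$frequency_axis$n_frequencies, x$seed))
  invisible(x)
}

#' Generate a synthetic scan cohort
#'
#' Emulates the cohort design of the third-generation UM-style phantom
#' protocol: for each randomized phantom geometry, one tumour scan per
#' tumour diameter with the tumour at a fixed per-phantom position, plus one
#' healthy scan of the same phantom (carrying the paired nominal tumour
#' geometry in its metadata). Phantom geometry parameters are drawn from
#' documented ranges under the given seed; the tumour centre is kept at
#' least one (largest) tumour radius inside the breast boundary.
#'
#' @param n_phantoms Number of unique phantom geometries (>= 1).
#' @param tumour_diameters_mm Tumour diameters in millimetres (default the
#'   emulated protocol set 10, 15, 20, 25, 30); use `numeric(0)` for
#'   healthy-only cohorts.
#' @param geometry,freqs,grid Scan geometry, frequency axis and rasterization
#'   grid shared by every record.
#' @param noise_sigma,order Passed to [simulate_scan()].
#' @param seed Master seed; per-record seeds are derived from it.
#' @param n_fibro Number of fibroglandular inclusions per phantom (0, 1, 2).
#' @param include_healthy Generate one healthy record per phantom (default
#'   TRUE).
#' @param fraction_healthy Optional value in [0, 1]: fraction of phantoms
#'   that contribute only their healthy record (their tumour records are
#'   skipped). `NULL` keeps the full per-phantom design.
#' @param amplitudes Named list of reflectivity amplitudes
#'   (`adipose`, `fibro`, `tumour`).
#' @return A list of [simulate_scan()] records; `attr(, "manifest")` holds a
#'   metadata data frame (one row per record).
#' @export
generate_cohort <- function(n_phantoms, tumour_diameters_mm = c(10, 15, 20, 25, 30),
                            geometry, freqs, grid, noise_sigma = 0, order = 1,
                            seed = 1, n_fibro = 1, include_healthy = TRUE,
                            fraction_healthy = NULL,
                            amplitudes = list(adipose = 10, fibro = 30,
                                              tumour = 50)) {
  .assert(n_phantoms >= 1, "n_phantoms must be >= 1")
  .assert(n_fibro %in% 0:2, "n_fibro must be 0, 1 or 2")
  if (!is.null(fraction_healthy)) {
    .assert(is.numeric(fraction_healthy) && fraction_healthy >= 0 &&
              fraction_healthy <= 1, "fraction_healthy must be in [0, 1]")
  }
  tumour_radii <- tumour_diameters_mm / 2 / 1000
  max_tr <- if (length(tumour_radii)) max(tumour_radii) else 0.015
  geoms <- .with_seed(seed, {
    lapply(seq_len(n_phantoms), function(i) {
      br <- stats::runif(1, 0.045, 0.065)
      bc <- stats::runif(2, -0.01, 0.01)
      # tumour fixed per phantom, >= one largest-tumour radius inside the disc
      tmax <- br - 2 * max_tr
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * max(tmax, 0.001)
      tc <- bc + rad * c(cos(ang), sin(ang))
      fibro <- NULL
      if (n_fibro > 0) {
        fibro <- lapply(seq_len(n_fibro), function(j) {
          fr <- stats::runif(1, 0.010, 0.020)
          fang <- stats::runif(1, 0, 2 * pi)
          frad <- sqrt(stats::runif(1)) * max(br - fr - 0.005, 0.001)
          list(centre = bc + frad * c(cos(fang), sin(fang)), radius = fr,
               amplitude = amplitudes$fibro)
        })
      }
      list(breast_centre = bc, breast_radius = br, tumour_centre = tc,
           fibro = fibro)
    })
  })
  healthy_only <- rep(FALSE, n_phantoms)
  if (!is.null(fraction_healthy)) {
    healthy_only[seq_len(round(fraction_healthy * n_phantoms))] <- TRUE
  }
  records <- list()
  rec_seed <- as.integer(seed)
  for (i in seq_len(n_phantoms)) {
    gm <- geoms[[i]]
    base_args <- list(breast_centre = gm$breast_centre,
                      breast_radius = gm$breast_radius,
                      breast_amplitude = amplitudes$adipose,
                      fibro = gm$fibro)
    nominal <- list(centre = gm$tumour_centre, radius = max_tr)
    if (!healthy_only[i]) {
      for (tr in tumour_radii) {
        rec_seed <- rec_seed + 1L
        spec <- do.call(phantom_spec, c(base_args, list(
          tumour = list(centre = gm$tumour_centre, radius = tr,
                        amplitude = amplitudes$tumour))))
        records[[length(records) + 1L]] <- simulate_scan(
          spec, geometry, freqs, grid, noise_sigma = noise_sigma,
          order = order, seed = rec_seed,
          id = sprintf("p%02d_t%02.0fmm", i, 2000 * tr))
      }
    }
    if (include_healthy) {
      rec_seed <- rec_seed + 1L
      spec <- do.call(phantom_spec, base_args)
      records[[length(records) + 1L]] <- simulate_scan(
        spec, geometry, freqs, grid, noise_sigma = noise_sigma, order = order,
        seed = rec_seed, id = sprintf("p%02d_healthy", i),
        nominal_tumour = nominal)
    }
  }
  attr(records, "manifest") <- cohort_manifest(records)
  records
}

#' Cohort manifest table
#'
#' One row of metadata per scan record; the schema doubles as the adapter
#' contract for importing externally measured scan metadata.
#'
#' @param records A list of [simulate_scan()] records.
#' @return Data frame with columns `id`, `has_tumour`, `tumour_x_m`,
#'   `tumour_y_m`, `tumour_radius_m`, `breast_radius_m`, `delta_r_m`,
#'   `seed`.
#' @export
cohort_manifest <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    md <- r$metadata
    data.frame(id = r$id, has_tumour = md$has_tumour,
               tumour_x_m = md$tumour_centre[1],
               tumour_y_m = md$tumour_centre[2],
               tumour_radius_m = md$tumour_radius,
               breast_radius_m = if (is.null(md$breast_boundary_radius))
                 NA_real_ else md$breast_boundary_radius,
               delta_r_m = md$positioning_uncertainty,
               seed = r$seed)
  }))
}
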