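# Image-quality metrics and rule-based tumour detection.
#
# SCR (signal-to-clutter ratio, dB): 20 log10 of the ratio between the
# maximum image magnitude inside the target (tumour) region and the maximum
# magnitude in the clutter region. The target region is the disc of radius
# r_tum + delta_r about the known tumour centre (the same radius used by the
# localization acceptance rule); the clutter region is everything else
# inside the breast boundary (or the whole image, configurably).
#
# LE (localization error, metres): distance from the global magnitude
# maximum to the known tumour centre.

#' Phantom ground-truth metadata
#'
#' Ground truth used to score reconstructions. Healthy phantoms carry the
#' *nominal* tumour geometry of their paired tumour scan (`has_tumour =
#' FALSE` but `tumour_centre`/`tumour_radius` set): the detection rule for
#' healthy images evaluates the SCR over the region the tumour would occupy,
#' making the false-positive rule computable with the same geometry.
#'
#' @param has_tumour Logical.
#' @param tumour_centre Length-2 (x, y) metres; required (nominal position
#'   for healthy phantoms).
#' @param tumour_radius Tumour radius in metres (> 0).
#' @param positioning_uncertainty Tumour positioning uncertainty delta_r in
#'   metres (default 0.004, the 4 mm of the emulated scan protocol).
#' @param breast_boundary_radius Radius of the breast boundary circle,
#'   metres, or `NULL` to evaluate clutter over the whole image.
#' @param breast_centre Centre of the breast boundary circle (default
#'   origin).
#' @return An object of class `phantom_metadata`.
#' @export
phantom_metadata <- function(has_tumour, tumour_centre, tumour_radius,
                             positioning_uncertainty = 0.004,
                             breast_boundary_radius = NULL,
                             breast_centre = c(0, 0)) {
  .assert(is.logical(has_tumour) && length(has_tumour) == 1,
          "has_tumour must be a single logical")
  .assert(length(tumour_centre) == 2 && all(is.finite(tumour_centre)),
          "tumour_centre must be a finite length-2 point (nominal for healthy phantoms)")
  .assert(is.numeric(tumour_radius) && tumour_radius > 0,
          "tumour_radius must be positive (metres)")
  .assert(is.numeric(positioning_uncertainty) && positioning_uncertainty > 0,
          "positioning_uncertainty must be positive (metres)")
  if (!is.null(breast_boundary_radius)) {
    .assert(breast_boundary_radius > 0, "breast_boundary_radius must be positive")
  }
  structure(list(has_tumour = has_tumour,
                 tumour_centre = as.numeric(tumour_centre),
                 tumour_radius = as.numeric(tumour_radius),
                 positioning_uncertainty = as.numeric(positioning_uncertainty),
                 breast_boundary_radius = breast_boundary_radius,
                 breast_centre = as.numeric(breast_centre)),
            class = "phantom_metadata")
}

# distance of every pixel centre from a point, as an (n_y, n_x) matrix
.pixel_dist <- function(grid, centre) {
  d <- sqrt((grid$pixel_xy[, 1] - centre[1])^2 +
              (grid$pixel_xy[, 2] - centre[2])^2)
  matrix(d, grid$n_y, grid$n_x)
}

#' Signal-to-clutter ratio (dB)
#'
#' `20 * log10(Tmax / Cmax)` with `Tmax` the maximum image magnitude in the
#' target disc (radius `tumour_radius + positioning_uncertainty` about the
#' known or nominal tumour centre) and `Cmax` the maximum magnitude over the
#' clutter region.
#'
#' @param image A [reconstructed_image()].
#' @param metadata A [phantom_metadata()] (supplies the target disc; for
#'   healthy phantoms this is the paired nominal tumour geometry).
#' @param clutter_region `"breast"` (default): clutter is every pixel inside
#'   the breast boundary circle and outside the target disc (falls back to
#'   the whole image when no boundary radius is set); `"image"`: all pixels
#'   outside the target disc.
#' @return SCR in dB. Degenerate images warn: `+Inf` when only the clutter
#'   maximum is zero, `-Inf` when the whole evaluation region is zero (no
#'   target response).
#' @export
scr <- function(image, metadata, clutter_region = c("breast", "image")) {
  .assert(inherits(image, "reconstructed_image"),
          "image must be a reconstructed_image")
  .assert(inherits(metadata, "phantom_metadata"),
          "metadata must be a phantom_metadata")
  clutter_region <- match.arg(clutter_region)
  if (is.null(metadata$tumour_centre)) {
    stop("SCR requires a target region: metadata must carry the (nominal) tumour centre",
         call. = FALSE)
  }
  grid <- image$grid
  mag <- Mod(image$intensity)
  r_target <- metadata$tumour_radius + metadata$positioning_uncertainty
  d_t <- .pixel_dist(grid, metadata$tumour_centre)
  target <- d_t <= r_target
  .assert(any(target), "target region contains no pixels (grid too coarse?)")
  clutter <- !target
  if (clutter_region == "breast" && !is.null(metadata$breast_boundary_radius)) {
    d_b <- .pixel_dist(grid, metadata$breast_centre)
    clutter <- clutter & (d_b <= metadata$breast_boundary_radius)
  }
  .assert(any(clutter), "clutter region contains no pixels")
  tmax <- max(mag[target])
  cmax <- max(mag[clutter])
  if (tmax == 0 && cmax == 0) {
    warning("image is identically zero over the evaluation region; SCR is -Inf")
    return(-Inf)
  }
  if (cmax == 0) {
    warning("clutter maximum is zero; SCR is +Inf")
    return(Inf)
  }
  20 * log10(tmax / cmax)
}

# argmax of |I| with deterministic tie-break: lowest row, then lowest column.
.argmax_pixel <- function(image) {
  mag <- Mod(image$intensity)
  idx <- which(mag == max(mag), arr.ind = TRUE)
  if (nrow(idx) > 1) {
    warning("tie at the image maximum; using the lowest row, then column index")
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  }
  idx[1, ]
}

#' Localization error (metres)
#'
#' Euclidean distance from the pixel centre of the global image-magnitude
#' maximum to the known tumour centre. Ties at the maximum are broken
#' deterministically (lowest row, then column) with a warning.
#'
#' @inheritParams scr
#' @return LE in metres.
#' @export
localization_error <- function(image, metadata) {
  .assert(inherits(image, "reconstructed_image"),
          "image must be a reconstructed_image")
  .assert(inherits(metadata, "phantom_metadata"),
          "metadata must be a phantom_metadata")
  .assert(isTRUE(metadata$has_tumour),
          "localization error is defined only for tumour-containing phantoms")
  ij <- .argmax_pixel(image)
  r_max <- c(image$grid$x[ij[2]], image$grid$y[ij[1]])
  sqrt(sum((r_max - metadata$tumour_centre)^2))
}

#' Detection rule label
#'
#' The rule table applied to precomputed metrics. Healthy phantom:
#' `SCR >= threshold` is a false positive, otherwise a true negative.
#' Tumour phantom: `SCR < threshold` is a false negative; with
#' `SCR >= threshold`, a localization error within `le_tol_m`
#' (`tumour_radius + positioning_uncertainty`, boundary inclusive) is a true
#' positive and anything farther is counted as a false negative.
#'
#' @param has_tumour Logical vector.
#' @param scr_db SCR values in dB.
#' @param le_m Localization errors in metres (ignored for healthy entries;
#'   may be `NA` there).
#' @param le_tol_m Localization tolerance(s) in metres.
#' @param scr_threshold_db SCR decision threshold in dB (default 1.5).
#' @return Character vector of labels in `TP`, `FP`, `TN`, `FN`.
#' @export
detection_label <- function(has_tumour, scr_db, le_m, le_tol_m,
                            scr_threshold_db = 1.5) {
  n <- length(has_tumour)
  scr_db <- rep_len(scr_db, n); le_m <- rep_len(le_m, n)
  le_tol_m <- rep_len(le_tol_m, n)
  pos <- scr_db >= scr_threshold_db
  out <- character(n)
  out[!has_tumour & pos] <- "FP"
  out[!has_tumour & !pos] <- "TN"
  out[has_tumour & !pos] <- "FN"
  hit <- has_tumour & pos
  if (any(hit)) {
    .assert(all(is.finite(le_m[hit])),
            "tumour-labelled phantoms need a localization error to classify")
    out[hit] <- ifelse(le_m[hit] <= le_tol_m[hit], "TP", "FN")
  }
  out
}

#' Classify a reconstruction as TP/FP/TN/FN
#'
#' Computes the SCR (and, for tumour phantoms, the localization error) of an
#' image and applies the detection rule of [detection_label()].
#'
#' @inheritParams scr
#' @param scr_threshold_db SCR decision threshold in dB (default 1.5).
#' @return An object of class `detection_result`: `scr_db`, `le_m` (`NA` for
#'   healthy phantoms), `le_tol_m`, `label`.
#' @export
classify_detection <- function(image, metadata, scr_threshold_db = 1.5,
                               clutter_region = c("breast", "image")) {
  s <- scr(image, metadata, clutter_region = clutter_region)
  le_tol <- metadata$tumour_radius + metadata$positioning_uncertainty
  le <- if (isTRUE(metadata$has_tumour)) {
    localization_error(image, metadata)
  } else {
    NA_real_
  }
  label <- detection_label(metadata$has_tumour, s, le, le_tol,
                           scr_threshold_db)
  structure(list(scr_db = s, le_m = le, le_tol_m = le_tol, label = label,
                 scr_threshold_db = scr_threshold_db),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s (SCR %.2f dB, LE %s)\n", x$label,
              x$scr_db,
              if (is.na(x$le_m)) "n/a" else sprintf("%.1f mm", 1e3 * x$le_m)))
  invisible(x)
}

#' Diagnostic summary of a detection cohort
#'
#' Counts TP/FP/TN/FN labels and reports sensitivity `TP / (TP + FN)` and
#' specificity `TN / (TN + FP)`. Rates with an empty denominator are `NA`
#' and flagged. When tumour diameters are supplied, a per-diameter
#' sensitivity table is included.
#'
#' @param labels Character vector of labels (`TP`/`FP`/`TN`/`FN`), or a list
#'   of `detection_result`s.
#' @param tumour_diameter_mm Optional numeric vector (same length) of tumour
#'   diameters for the per-size sensitivity breakdown; `NA` for healthy
#'   entries.
#' @return An object of class `diagnostic_summary` with `counts`,
#'   `sensitivity`, `specificity`, flags `sensitivity_defined` /
#'   `specificity_defined`, and optional `by_size` data frame.
#' @export
diagnostic_summary <- function(labels, tumour_diameter_mm = NULL) {
  if (is.list(labels)) {
    labels <- vapply(labels, function(r) r$label, character(1))
  }
  .assert(length(labels) >= 1, "empty result list")
  .assert(all(labels %in% c("TP", "FP", "TN", "FN")),
          "labels must be TP, FP, TN or FN")
  counts <- c(TP = sum(labels == "TP"), FP = sum(labels == "FP"),
              TN = sum(labels == "TN"), FN = sum(labels == "FN"))
  sens_def <- (counts["TP"] + counts["FN"]) > 0
  spec_def <- (counts["TN"] + counts["FP"]) > 0
  sens <- if (sens_def) unname(counts["TP"] / (counts["TP"] + counts["FN"])) else NA_real_
  spec <- if (spec_def) unname(counts["TN"] / (counts["TN"] + counts["FP"])) else NA_real_
  by_size <- NULL
  if (!is.null(tumour_diameter_mm)) {
    .assert(length(tumour_diameter_mm) == length(labels),
            "tumour_diameter_mm must match labels in length")
    tum <- labels %in% c("TP", "FN")
    if (any(tum)) {
      sizes <- sort(unique(tumour_diameter_mm[tum]))
      by_size <- data.frame(
        diameter_mm = sizes,
        n = vapply(sizes, function(s) sum(tum & tumour_diameter_mm == s), 0L),
        sensitivity = vapply(sizes, function(s) {
          sel <- tum & tumour_diameter_mm == s
          sum(labels[sel] == "TP") / sum(sel)
        }, 0)
      )
    }
  }
  structure(list(counts = counts, sensitivity = sens, specificity = spec,
                 sensitivity_defined = unname(sens_def),
                 specificity_defined = unname(spec_def), by_size = by_size),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("<diagnostic_summary> TP %d FP %d TN %d FN %d | sens %s, spec %s\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"],
              if (x$sensitivity_defined) sprintf("%.3f", x$sensitivity) else "undefined",
              if (x$specificity_defined) sprintf("%.3f", x$specificity) else "undefined"))
  if (!is.null(x$by_size)) {
    print(x$by_size, row.names = FALSE)
  }
  invisible(x)
}

#' ROC sweep over SCR thresholds
#'
#' Re-applies the detection rule of [detection_label()] at each SCR
#' threshold (the localization rule is unchanged) and reports sensitivity
#' and false-positive rate. By construction both are non-increasing as the
#' threshold increases.
#'
#' @param metrics Data frame with columns `has_tumour` (logical), `scr_db`,
#'   `le_m` (may be `NA` for healthy rows) and `le_tol_m` — e.g. the metrics
#'   table written by [run_pipeline()], or per-image results collected from
#'   [classify_detection()].
#' @param thresholds_db Thresholds in dB (default: 1000 linearly spaced
#'   values in [0, 30]).
#' @return Data frame with columns `threshold_db`, `sensitivity`, `fpr`
#'   (1 - specificity); `NA` rates when the cohort lacks the class.
#' @export
roc_curve <- function(metrics, thresholds_db = seq(0, 30, length.out = 1000)) {
  .assert(is.data.frame(metrics) &&
            all(c("has_tumour", "scr_db", "le_m", "le_tol_m") %in% names(metrics)),
          "metrics must have columns has_tumour, scr_db, le_m, le_tol_m")
  .assert(nrow(metrics) >= 1, "empty cohort")
  n_pos <- sum(metrics$has_tumour)
  n_neg <- sum(!metrics$has_tumour)
  sens <- fpr <- rep(NA_real_, length(thresholds_db))
  for (i in seq_along(thresholds_db)) {
    lab <- detection_label(metrics$has_tumour, metrics$scr_db, metrics$le_m,
                           metrics$le_tol_m, thresholds_db[i])
    if (n_pos > 0) sens[i] <- sum(lab == "TP") / n_pos
    if (n_neg > 0) fpr[i] <- sum(lab == "FP") / n_neg
  }
  data.frame(threshold_db = thresholds_db, sensitivity = sens, fpr = fpr)
}
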