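# File I/O: delimited-text interchange for S-parameters and images,
# RDS containers for whole scan records, and PNG image export.

#' Write an S-parameter set as delimited text
#'
#' Portable interchange format: one row per (position, frequency) pair with
#' real/imaginary columns, preceded by commented header lines carrying the
#' propagation speed.
#'
#' @param sp A [sparameter_set()].
#' @param path Output path (tab-separated).
#' @export
write_sparams_tsv <- function(sp, path) {
  .assert(inherits(sp, "sparameter_set"), "sp must be a sparameter_set")
  n_pos <- sp$geometry$n_positions
  n_f <- sp$frequency_axis$n_frequencies
  df <- data.frame(
    position_index = rep(seq_len(n_pos), times = n_f),
    antenna_x_m = rep(sp$geometry$positions[, 1], times = n_f),
    antenna_y_m = rep(sp$geometry$positions[, 2], times = n_f),
    frequency_hz = rep(sp$frequency_axis$frequencies, each = n_pos),
    s11_real = as.vector(Re(sp$values)),
    s11_imag = as.vector(Im(sp$values))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# propagation_speed_m_s=%.17g", sp$geometry$speed), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an S-parameter set from delimited text
#' @param path A file written by [write_sparams_tsv()].
#' @return A [sparameter_set()].
#' @export
read_sparams_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  .assert(grepl("^# propagation_speed_m_s=", hdr),
          "missing propagation-speed header line")
  speed <- as.numeric(sub("^# propagation_speed_m_s=", "", hdr))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  pos_idx <- sort(unique(df$position_index))
  fr <- sort(unique(df$frequency_hz))
  df <- df[order(df$frequency_hz, df$position_index), ]
  vals <- matrix(complex(real = df$s11_real, imaginary = df$s11_imag),
                 nrow = length(pos_idx), ncol = length(fr))
  first <- df[df$frequency_hz == fr[1], ]
  geom <- scan_geometry(cbind(first$antenna_x_m, first$antenna_y_m),
                        speed = speed)
  sparameter_set(vals, geom, frequency_axis(fr))
}

#' Write/read a scan record as an RDS container
#'
#' Run-time binary container for whole records (target scan, reference
#' triplet, metadata). For text interchange use [write_sparams_tsv()] and
#' [write_manifest()].
#'
#' @param record A [simulate_scan()] record.
#' @param path Output `.rds` path.
#' @export
write_scan_record <- function(record, path) {
  .assert(inherits(record, "scan_record"), "record must be a scan_record")
  saveRDS(record, path)
  invisible(path)
}

#' @rdname write_scan_record
#' @export
read_scan_record <- function(path) {
  rec <- readRDS(path)
  .assert(inherits(rec, "scan_record"), "file does not contain a scan_record")
  rec
}

#' Write/read a cohort manifest
#' @param manifest Data frame from [cohort_manifest()].
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path)
}

#' Export a reconstructed image to PNG
#'
#' Writes the linearly scaled image magnitude (max-normalized) as a
#' greyscale PNG, with row 1 of the file at the top (largest y).
#' Requires the `png` package.
#'
#' @param image A [reconstructed_image()].
#' @param path Output `.png` path.
#' @export
export_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the png package is required for PNG export", call. = FALSE)
  }
  m <- image_magnitude(image, normalize = TRUE)
  png::writePNG(m[rev(seq_len(nrow(m))), , drop = FALSE], path)
  invisible(path)
}

#' Write a reconstructed image as delimited text
#'
#' One row per pixel: indices, coordinates, real/imaginary parts and
#' magnitude.
#'
#' @param image A [reconstructed_image()].
#' @param path Output path (tab-separated).
#' @export
write_image_tsv <- function(image, path) {
  g <- image$grid
  df <- data.frame(
    iy = rep(seq_len(g$n_y), times = g$n_x),
    ix = rep(seq_len(g$n_x), each = g$n_y),
    x_m = g$pixel_xy[, 1], y_m = g$pixel_xy[, 2],
    re = as.vector(Re(image$intensity)),
    im = as.vector(Im(image$intensity)),
    magnitude = as.vector(Mod(image$intensity))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# algorithm=%s", image$algorithm), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
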