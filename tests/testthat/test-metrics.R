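# SCR, localization error, the detection rule, summaries and the ROC sweep.

# image with chosen magnitudes at chosen pixels on an otherwise tiny floor
make_image <- function(grid, peaks, floor = 0) {
  m <- matrix(complex(real = floor), grid$n_y, grid$n_x)
  for (p in peaks) m[p$iy, p$ix] <- p$value
  reconstructed_image(m, grid, "DAS")
}

tumour_md <- function(grid, centre = c(0.02, 0.01), radius = 0.0075,
                      has_tumour = TRUE) {
  phantom_metadata(has_tumour = has_tumour, tumour_centre = centre,
                   tumour_radius = radius, positioning_uncertainty = 0.004,
                   breast_boundary_radius = 0.055)
}

test_that("SCR is 20 log10 of the target/clutter maximum ratio", {
  grid <- image_grid(c(-0.06, 0.06), c(-0.06, 0.06), 24, 24)
  md <- tumour_md(grid)
  # pixel indices: centre pixel of the target disc, and a far clutter pixel
  it <- which.min(bmsradar:::.pixel_dist(grid, md$tumour_centre))
  ic <- which.min(bmsradar:::.pixel_dist(grid, c(-0.03, -0.02)))
  iyt <- (it - 1) %% 24 + 1; ixt <- (it - 1) %/% 24 + 1
  iyc <- (ic - 1) %% 24 + 1; ixc <- (ic - 1) %/% 24 + 1
  mk <- function(tval, cval) make_image(grid, list(
    list(iy = iyt, ix = ixt, value = tval),
    list(iy = iyc, ix = ixc, value = cval)))
  expect_equal(scr(mk(1, 1), md), 0)
  expect_equal(scr(mk(10, 1), md), 20)
  expect_equal(scr(mk(2, 1), md), 20 * log10(2))
  # invariant under global positive scaling
  expect_equal(scr(mk(3.7, 1.1), md), scr(mk(2 * 3.7, 2 * 1.1), md))
  # zero clutter -> +Inf with warning
  expect_warning(v <- scr(mk(1, 0), md), "Inf")
  expect_identical(v, Inf)
  # identically zero image -> -Inf (no target response, not a detection)
  expect_warning(v0 <- scr(mk(0, 0), md), "zero")
  expect_identical(v0, -Inf)
})

test_that("localization error is the distance from the magnitude argmax", {
  grid <- image_grid(c(-0.06, 0.06), c(-0.06, 0.06), 24, 24)
  md <- tumour_md(grid)
  # single nonzero pixel at a known offset: exact Euclidean distance
  iy <- 5; ix <- 20
  img <- make_image(grid, list(list(iy = iy, ix = ix, value = 1)))
  want <- sqrt(sum((c(grid$x[ix], grid$y[iy]) - md$tumour_centre)^2))
  expect_equal(localization_error(img, md), want)
  # max at the tumour-centre pixel: at most half-pixel quantization
  it <- which.min(bmsradar:::.pixel_dist(grid, md$tumour_centre))
  img2 <- make_image(grid, list(list(iy = (it - 1) %% 24 + 1,
                                     ix = (it - 1) %/% 24 + 1, value = 1)))
  expect_lte(localization_error(img2, md),
             sqrt(grid$dx^2 + grid$dy^2) / 2)
  # invariant under monotone transforms that keep the argmax
  img3 <- make_image(grid, list(list(iy = iy, ix = ix, value = 2),
                                list(iy = 1, ix = 1, value = 1)))
  img3_sq <- reconstructed_image(img3$intensity^2, grid, "DAS")
  expect_equal(localization_error(img3, md),
               localization_error(img3_sq, md))
  # ties break to lowest row, then column, with a warning
  img4 <- make_image(grid, list(list(iy = 10, ix = 3, value = 1),
                                list(iy = 2, ix = 17, value = 1)))
  expect_warning(le <- localization_error(img4, md), "tie")
  expect_equal(le, sqrt(sum((c(grid$x[17], grid$y[2]) - md$tumour_centre)^2)))
  # healthy metadata refuses
  expect_error(localization_error(img, tumour_md(grid, has_tumour = FALSE)),
               "tumour")
})

test_that("the detection rule reproduces the full truth table", {
  tol <- 0.0115 # r_tum + delta_r
  # healthy: only the SCR rule applies
  expect_equal(detection_label(FALSE, 2.0, NA, tol), "FP")
  expect_equal(detection_label(FALSE, 1.5, NA, tol), "FP") # boundary: >= is positive
  expect_equal(detection_label(FALSE, 1.0, NA, tol), "TN")
  # tumour: SCR below threshold is a miss regardless of LE
  expect_equal(detection_label(TRUE, 1.0, 0.001, tol), "FN")
  expect_equal(detection_label(TRUE, 1.0, 0.05, tol), "FN")
  # tumour, SCR above threshold: LE decides, boundary inclusive
  expect_equal(detection_label(TRUE, 3.0, 0.005, tol), "TP")
  expect_equal(detection_label(TRUE, 3.0, tol, tol), "TP")
  expect_equal(detection_label(TRUE, 3.0, tol + 1e-9, tol), "FN")
  # vectorized over a mixed cohort
  expect_equal(
    detection_label(c(TRUE, FALSE, TRUE, FALSE), c(5, 5, 0, 0),
                    c(0.001, NA, 0.001, NA), tol),
    c("TP", "FP", "FN", "TN"))
})

test_that("classify_detection applies the rule to computed image metrics", {
  grid <- image_grid(c(-0.06, 0.06), c(-0.06, 0.06), 24, 24)
  md <- tumour_md(grid)
  it <- which.min(bmsradar:::.pixel_dist(grid, md$tumour_centre))
  iyt <- (it - 1) %% 24 + 1; ixt <- (it - 1) %/% 24 + 1
  ic <- which.min(bmsradar:::.pixel_dist(grid, c(-0.03, -0.02)))
  iyc <- (ic - 1) %% 24 + 1; ixc <- (ic - 1) %/% 24 + 1
  strong <- make_image(grid, list(list(iy = iyt, ix = ixt, value = 10),
                                  list(iy = iyc, ix = ixc, value = 1)))
  weak <- make_image(grid, list(list(iy = iyt, ix = ixt, value = 1),
                                list(iy = iyc, ix = ixc, value = 1)))
  expect_equal(classify_detection(strong, md)$label, "TP")
  # flat target/clutter maxima tie at the argmax; label is still a miss
  expect_warning(lab_weak <- classify_detection(weak, md)$label, "tie")
  expect_equal(lab_weak, "FN")
  md_h <- tumour_md(grid, has_tumour = FALSE)
  expect_equal(classify_detection(strong, md_h)$label, "FP")
  expect_equal(classify_detection(weak, md_h)$label, "TN")
})

test_that("diagnostic summary counts and flags undefined rates", {
  s <- diagnostic_summary(c("TP", "TP", "FN", "FN", "TN", "FP"))
  expect_equal(unname(s$counts), c(2L, 1L, 1L, 2L))
  expect_equal(s$sensitivity, 0.5)
  expect_equal(s$specificity, 0.5)
  s2 <- diagnostic_summary(c("TP", "TP"))
  expect_equal(s2$sensitivity, 1)
  expect_false(s2$specificity_defined)
  expect_true(is.na(s2$specificity))
  # per-size sensitivity table
  s3 <- diagnostic_summary(c("TP", "FN", "TP", "TP", "TN"),
                           tumour_diameter_mm = c(10, 10, 30, 30, NA))
  expect_equal(s3$by_size$sensitivity, c(0.5, 1))
  expect_equal(s3$by_size$diameter_mm, c(10, 30))
})

test_that("ROC sweep matches hand enumeration and is monotone", {
  tol <- 0.0115
  cohort <- data.frame(
    has_tumour = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    scr_db = c(5, 10, 0.5, 2, 8, -1),
    le_m = c(0.002, 0.004, 0.001, NA, NA, NA),
    le_tol_m = tol)
  roc <- roc_curve(cohort)
  expect_equal(nrow(roc), 1000)
  # independent enumeration at every threshold
  for (i in seq(1, 1000, by = 97)) {
    thr <- roc$threshold_db[i]
    tp <- sum(cohort$has_tumour & cohort$scr_db >= thr &
                cohort$le_m <= tol, na.rm = TRUE)
    fp <- sum(!cohort$has_tumour & cohort$scr_db >= thr)
    expect_equal(roc$sensitivity[i], tp / 3)
    expect_equal(roc$fpr[i], fp / 3)
  }
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$fpr) <= 0))
  # threshold 0: every positive-SCR healthy image is a false positive
  expect_equal(roc$fpr[1], 2 / 3)
  # thresholds above the maximum SCR: nothing is called positive
  expect_equal(roc$sensitivity[1000], 0)
  expect_equal(roc$fpr[1000], 0)
})
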