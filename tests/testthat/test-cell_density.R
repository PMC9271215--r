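# synthetic imaging plane: Gaussian somata on a dim noisy background
blob_image <- function(cells_xy, dims_px = c(200, 200), spacing = 2,
                       amp = 150, sigma_px = 1.5, bg = 20, noise = 3,
                       seed = 1) {
  img <- matrix(0, dims_px[1], dims_px[2])
  for (i in seq_len(nrow(cells_xy))) {
    cx <- cells_xy[i, 1] / spacing; cy <- cells_xy[i, 2] / spacing
    xs <- max(1, round(cx - 5)):min(dims_px[1], round(cx + 5))
    ys <- max(1, round(cy - 5)):min(dims_px[2], round(cy + 5))
    img[xs, ys] <- img[xs, ys] +
      amp * exp(-(outer((xs - cx)^2, (ys - cy)^2, `+`)) / (2 * sigma_px^2))
  }
  set.seed(seed)
  img + matrix(stats::rnorm(prod(dims_px), bg, noise), dims_px[1], dims_px[2])
}

# well-separated random points (hard-core process)
separated_points <- function(n, extent, min_sep, seed) {
  set.seed(seed)
  pts <- NULL
  while (is.null(pts) || nrow(pts) < n) {
    p <- stats::runif(2, min_sep, extent - min_sep)
    if (is.null(pts) ||
        min(sqrt(rowSums(sweep(pts, 2, p)^2))) > min_sep)
      pts <- rbind(pts, p)
  }
  pts
}

test_that("candidate detection finds radius-separated local maxima", {
  # constant image: no strict maxima above the floor
  expect_equal(nrow(detect_candidates(matrix(5, 50, 50), spacing = 2)), 0)

  # two blobs 20 um apart -> two candidates at the centres (+- 1 px)
  img <- blob_image(rbind(c(100, 100), c(120, 100)), noise = 0)
  det <- detect_candidates(img, radius_um = 8, spacing = 2)
  expect_equal(nrow(det), 2)
  expect_true(all(abs(sort(det$x_um) - c(100, 120)) <= 2 + 1e-9))
  expect_true(all(abs(det$y_um - 100) <= 2 + 1e-9))

  # 5 um apart (< 8 um radius): a single candidate survives
  img2 <- blob_image(rbind(c(100, 100), c(105, 100)), noise = 0)
  det2 <- detect_candidates(img2, radius_um = 8, spacing = 2)
  expect_equal(nrow(det2), 1)

  # plateau ties resolve deterministically (lexicographically smallest)
  flat <- matrix(0, 40, 40)
  flat[10:12, 10:12] <- 50
  d3 <- detect_candidates(flat, radius_um = 4, spacing = 1, floor = 10)
  expect_equal(nrow(d3), 1)
  expect_equal(c(d3$x_um, d3$y_um), c(9.5, 9.5))
})

test_that("candidate completeness: every bright truth cell is found", {
  pts <- separated_points(25, 400, 20, seed = 4)
  img <- blob_image(pts, seed = 5)
  det <- detect_candidates(img, radius_um = 8, spacing = 2)
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((det$x_um - pts[i, 1])^2 + (det$y_um - pts[i, 2])^2)
    expect_lte(min(d), 8)
  }
})

test_that("patch extraction builds the stated window geometry", {
  img <- blob_image(matrix(c(199, 199), 1), noise = 0)
  cand <- data.frame(x_um = 199, y_um = 199)
  p <- extract_patches(img, cand, spacing = 2)
  expect_equal(dim(p$small), c(101, 101))
  expect_equal(dim(p$large), c(201, 201))
  expect_equal(p$small_marker[51, 51], 1)
  expect_equal(sum(p$small_marker), 1)
  expect_equal(sum(p$large_marker), 1)
  expect_equal(unname(p$padded_fraction["small"]), 0)
  # the blob peaks at the window centre
  pk <- which(p$small == max(p$small), arr.ind = TRUE)
  expect_true(all(abs(pk - 51) <= 1))

  # corner candidate: zero-padded with the padded fraction reported
  pc <- extract_patches(img, data.frame(x_um = 2, y_um = 2), spacing = 2)
  expect_gt(unname(pc$padded_fraction["large"]), 0.4)
  expect_equal(pc$large[1, 1], 0)

  # uniform image resamples exactly to a uniform large window
  uni <- matrix(3, 300, 300)
  pu <- extract_patches(uni, data.frame(x_um = 300, y_um = 300), spacing = 2)
  expect_true(all(abs(pu$large - 3) < 1e-12 | pu$large == 0))

  expect_error(extract_patches(img, data.frame(x_um = 999, y_um = 0),
                               spacing = 2), "outside")

  # full-frame context at 201 x 201
  pf <- extract_patches(img, cand, spacing = 2, include_full_frame = TRUE)
  expect_equal(dim(pf$frame), c(201, 201))
  expect_equal(sum(pf$frame_marker), 1)
})

test_that("the baseline classifier separates somata from background peaks", {
  pts <- separated_points(20, 400, 25, seed = 11)
  img <- blob_image(pts, seed = 12)
  det <- detect_candidates(img, radius_um = 8, spacing = 2)
  cls <- classify_candidates(det, img, spacing = 2,
                             classifier = baseline_blob_classifier(min_contrast = 50))
  pos <- cls[cls$class == "pericyte", ]
  ev <- evaluate_detection(pos, data.frame(x_um = pts[, 1], y_um = pts[, 2]),
                           match_radius = 8)
  expect_gte(ev$f1, 0.95)

  # all-reject classifier yields zero positives
  rej <- classify_candidates(det, img, spacing = 2,
                             classifier = function(p, c) "other")
  expect_equal(sum(rej$class == "pericyte"), 0)

  # label multiset is invariant under candidate order
  perm <- sample(nrow(det))
  cls2 <- classify_candidates(det[perm, ], img, spacing = 2,
                              classifier = baseline_blob_classifier(min_contrast = 50))
  expect_equal(sort(table(cls$class)), sort(table(cls2$class)))

  # out-of-vocabulary labels are an error
  expect_error(classify_candidates(det, img, spacing = 2,
                                   classifier = function(p, c) "mystery"),
               "outside the class set")
})

test_that("conversion factors reproduce the printed worked example", {
  cf <- estimate_conversion_factor(840, 1769)
  expect_equal(cf$factor, 2.1)
  expect_equal(cf$pooled_ratio, 1769 / 840, tolerance = 1e-12)
  expect_equal(estimate_conversion_factor(100, 100)$factor, 1.0)
  roi <- data.frame(count_2d = rep(10, 5), count_3d = rep(21, 5))
  cfr <- estimate_conversion_factor(50, 105, roi)
  expect_equal(cfr$per_roi_mean, 2.1)
  expect_equal(cfr$per_roi_sd, 0)
  expect_error(estimate_conversion_factor(0, 10), "positive")
  # scale invariance of the pooled factor
  expect_equal(estimate_conversion_factor(840 * 3, 1769 * 3)$factor, 2.1)
  # bundled published factors
  expect_equal(unname(conversion_factors[c("cytoplasmic", "nuclear", "pericyte")]),
               c(1.4, 1.5, 2.1))
})

test_that("density conversion is arithmetic and names missing regions", {
  counts <- data.frame(region_id = c(1, 2), count = c(100, 40))
  vols <- c("1" = 1, "2" = 0.5)
  d <- compute_density(counts, estimate_conversion_factor(840, 1769), vols)
  expect_equal(d$density_mm3, c(100 * 2.1 / 1, 40 * 2.1 / 0.5))
  d1 <- compute_density(counts, 1.0, vols)
  expect_equal(d1$density_mm3, c(100, 80))
  expect_error(compute_density(data.frame(region_id = 3, count = 5), 2.1, vols),
               "3")
})

test_that("plane counting plus conversion recovers generator densities", {
  # 2D counting sees cells within a 5-um optical section every 50 um of
  # depth; the 3D/2D factor is calibrated once and then applied
  ann <- block_annotation(1, block_vox = c(50, 50, 80), spacing = 10)
  vol_mm3 <- prod(c(500, 500, 800)) / 1e9
  plane_z <- seq(12.5, 787.5, by = 25)
  count2d <- function(cells)
    sum(vapply(plane_z, function(z) sum(abs(cells$z_um - z) <= 2.5), 0))
  calib <- generate_cell_field(c("1" = 10000), ann, rng_seed = 999)
  factor <- estimate_conversion_factor(count2d(calib), nrow(calib))
  dens <- vapply(1:20, function(s) {
    cells <- generate_cell_field(c("1" = 500), ann, rng_seed = s)
    compute_density(data.frame(region_id = 1, count = count2d(cells)),
                    factor$pooled_ratio, c("1" = vol_mm3))$density_mm3
  }, 0)
  expect_lt(abs(mean(dens) / 500 - 1), 0.1)
})

test_that("greedy detection scoring tracks the optimal assignment", {
  expect_equal(evaluate_detection(data.frame(x_um = 1:3, y_um = 1:3),
                                  data.frame(x_um = 1:3, y_um = 1:3), 8)$f1, 1)
  expect_equal(evaluate_detection(data.frame(x_um = numeric(), y_um = numeric()),
                                  data.frame(x_um = 1, y_um = 1), 8)$f1, 0)
  set.seed(23)
  for (trial in 1:5) {
    det <- data.frame(x_um = stats::runif(120, 0, 400),
                      y_um = stats::runif(120, 0, 400))
    tru <- data.frame(x_um = stats::runif(100, 0, 400),
                      y_um = stats::runif(100, 0, 400))
    got <- evaluate_detection(det, tru, 8)
    opt <- oracle_optimal_matches(det, tru, 8)
    f1_opt <- 2 * (opt / 120) * (opt / 100) / ((opt / 120) + (opt / 100))
    expect_lte(abs(got$f1 - f1_opt), 0.02 + 1e-9)
  }
})
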