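test_that("vascular graph generation honours seed, emptiness and geometry", {
  spec0 <- synthetic_spec(n_seed_vessels = 0)
  expect_equal(nrow(generate_vascular_graph(spec0)$graph$segments), 0)

  spec <- synthetic_spec(volume_extent = c(200, 200, 200),
                         voxel_spacing = c(1, 1, 1), n_seed_vessels = 4,
                         rng_seed = 11)
  g1 <- generate_vascular_graph(spec)$graph
  g2 <- generate_vascular_graph(spec)$graph
  expect_identical(g1, g2)

  # straight-line mode: no branching, no tortuosity -> every polyline
  # is collinear with exactly 2 distinct endpoints
  specs <- synthetic_spec(volume_extent = c(300, 300, 300),
                          voxel_spacing = c(1, 1, 1), n_seed_vessels = 5,
                          tortuosity = 0, branch_probability = 0,
                          rng_seed = 2)
  gs <- generate_vascular_graph(specs)$graph
  expect_gt(nrow(gs$segments), 0)
  for (i in seq_len(nrow(gs$segments))) {
    p <- gs$polylines[[i]]
    a <- p[1, ]; b <- p[nrow(p), ]
    u <- (b - a) / sqrt(sum((b - a)^2))
    dev <- apply(p, 1, function(q) {
      w <- q - a
      sqrt(sum((w - sum(w * u) * u)^2))
    })
    expect_lt(max(dev), 1e-8)
  }
  # all coordinates inside the stated extent
  pts <- do.call(rbind, gs$polylines)
  expect_true(all(pts >= -1e-9 & sweep(pts, 2, specs$volume_extent) <= 1e-9))

  # extent too small for the radius is an explicit failure
  expect_error(generate_vascular_graph(
    synthetic_spec(volume_extent = c(10, 10, 10), radius_range = c(4, 6))),
    "too small")
})

test_that("rasterization matches brute-force tube geometry", {
  dims <- c(40, 30, 30)
  sp <- c(1, 1, 1)
  a <- c(0, 15, 15); b <- c(40, 15, 15); r <- 4
  g <- tube_graph(a, b, radius = r)
  spec <- synthetic_spec(volume_extent = dims, voxel_spacing = sp,
                         n_seed_vessels = 0, noise_sd = 0, psf_sigma = 0)
  tc <- rasterize_graph(list(graph = g), spec, channels = FALSE)
  expect_identical(unname(tc$mask$data), oracle_tube_mask(a, b, r, dims, sp))

  # measured radius at the centreline: 4 um within one voxel
  skel <- measure_radii(tc$mask, skeletonize(tc$mask))
  expect_true(all(abs(skel$radius_um - r) <= 1 + 1e-9))

  # sub-voxel tube flags a warning
  spec5 <- synthetic_spec(volume_extent = dims, voxel_spacing = c(1, 1, 5),
                          n_seed_vessels = 0, noise_sd = 0, psf_sigma = 0)
  tc5 <- rasterize_graph(list(graph = tube_graph(a, b, radius = 1)), spec5,
                         channels = FALSE)
  expect_true(tc5$subvoxel_warning)

  # empty graph: the two synthesised channels are statistically alike
  spec_e <- synthetic_spec(volume_extent = c(40, 40, 20),
                           voxel_spacing = c(1, 1, 1), n_seed_vessels = 0,
                           radius_range = c(2, 3), rng_seed = 5)
  tce <- rasterize_graph(generate_vascular_graph(spec_e), spec_e)
  expect_lt(abs(mean(tce$signal$data) - mean(tce$background$data)),
            3 * stats::sd(tce$signal$data) / sqrt(10))
})

test_that("noise-free tube volume agrees with analytic pi r^2 L", {
  dims <- c(60, 40, 40)
  g <- tube_graph(c(0, 20, 20), c(60, 20, 20), radius = 5)
  spec <- synthetic_spec(volume_extent = dims, voxel_spacing = c(1, 1, 1),
                         n_seed_vessels = 0, noise_sd = 0, psf_sigma = 0)
  tc <- rasterize_graph(list(graph = g), spec, channels = FALSE)
  expect_lt(abs(sum(tc$mask$data) / (pi * 25 * 60) - 1), 0.1)
})

test_that("cortex phantoms have the stated layer geometry", {
  expect_error(generate_cortex_phantom("slab", layer_fractions = 1),
               "at least 2")
  expect_error(generate_cortex_phantom("slab", layer_fractions = c(0.4, 0.4)),
               "sum to 1")

  ph <- generate_cortex_phantom("slab", layer_fractions = c(0.5, 0.5),
                                extent = c(100, 160, 60), spacing = 4)
  v1 <- sum(ph$data == 1)
  v2 <- sum(ph$data == 2)
  expect_equal(v1, v2, tolerance = 0.05)

  hc <- generate_cortex_phantom("half_cylinder",
                                layer_fractions = c(0.25, 0.25, 0.25, 0.25),
                                extent = c(300, 160, 80), spacing = 2,
                                inner_radius = 60)
  R <- attr(hc, "outer_radius"); r0 <- attr(hc, "inner_radius")
  ctr <- attr(hc, "axis_center")
  # layer-1 surface voxels sit at distance ~ R from the axis
  d <- dim(hc$data)
  cortex <- array(hc$data > 0, d)
  surf <- vasculomap:::.adjacent_to(!cortex, d) & hc$data == 1
  idx <- which(surf, arr.ind = TRUE)
  rho <- sqrt(((idx[, 1] - 0.5) * 2 - ctr[1])^2 + ((idx[, 2] - 0.5) * 2)^2)
  expect_lt(max(abs(rho - R)), 2 * 2)   # within two voxels
  # per-layer volumes match the analytic half-annulus within 2%
  vox_um3 <- prod(hc$spacing)
  for (l in 1:4) {
    ro <- R - (l - 1) / 4 * (R - r0)
    ri <- R - l / 4 * (R - r0)
    analytic <- pi / 2 * (ro^2 - ri^2) * 80
    expect_equal(sum(hc$data == l) * vox_um3, analytic, tolerance = 0.02)
  }
})

test_that("cell fields are Poisson with the requested rates", {
  ann <- block_annotation(2, block_vox = c(10, 10, 10), spacing = 10)
  # region volume = 10x10x10 vox * 1000 um3 = 0.001 mm3
  expect_equal(nrow(generate_cell_field(c("1" = 0, "2" = 0), ann, 1)), 0)
  expect_error(generate_cell_field(c("9" = 100), ann, 1), "9")
  expect_error(generate_cell_field(c("1" = -5), ann, 1), ">= 0")

  d <- 5000   # cells/mm3 -> mean 5 per draw in region 1
  counts <- vapply(1:100, function(s)
    sum(generate_cell_field(c("1" = d), ann, rng_seed = s)$region == 1), 0)
  expect_lt(abs(mean(counts) - 5), 3 * sqrt(5 / 100))

  # every point lands inside its region's voxels
  cells <- generate_cell_field(c("2" = 20000), ann, rng_seed = 3)
  ijk <- point_to_voxel(ann, as.matrix(cells[, c("x_um", "y_um", "z_um")]))
  labs <- ann$data[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
  expect_true(all(labs == 2L))
})

test_that("per-region counts pass a chi-squared Poisson GOF check", {
  ann <- block_annotation(1, block_vox = c(10, 10, 10), spacing = 10)
  lambda <- 8  # 8000 cells/mm3 x 0.001 mm3
  counts <- vapply(1:200, function(s)
    nrow(generate_cell_field(c("1" = 8000), ann, rng_seed = 1000 + s)), 0)
  # bin the observed counts against Poisson(lambda) expectations
  brks <- c(-0.5, 3.5, 5.5, 7.5, 9.5, 11.5, Inf)
  obs <- table(cut(counts, brks))
  pr <- diff(stats::ppois(brks, lambda))
  chi <- sum((as.numeric(obs) - 200 * pr)^2 / (200 * pr))
  expect_lt(chi, stats::qchisq(0.99, df = length(pr) - 1))
})

test_that("the fixture suite is deterministic and self-describing", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  m1 <- make_fixture_suite(d1)
  m2 <- make_fixture_suite(d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 10)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  expect_true(all(c("spur_graph", "gap_8", "gap_12", "tube_r2", "tube_r3",
                    "tube_r5", "lattice", "half_cylinder") %in% names(m1)))
  # lattice fixture has equal edge counts along each axis
  lat <- fixture_lattice_graph(n = 3, pitch = 100)
  dirs <- vapply(seq_len(nrow(lat$segments)), function(i) {
    p <- lat$polylines[[i]]
    which.max(abs(p[nrow(p), ] - p[1, ]))
  }, 0L)
  expect_equal(as.numeric(table(dirs)), rep(18, 3))
})
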