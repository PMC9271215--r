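test_that("skeletonization preserves topology and centres tubes", {
  # empty mask -> empty skeleton -> empty graph
  empty <- voxel_volume(array(FALSE, c(10, 10, 10)), c(1, 1, 1))
  sk0 <- skeletonize(empty)
  expect_equal(nrow(sk0$voxels), 0)
  expect_equal(nrow(build_graph(sk0)$segments), 0)

  # anisotropic input is rejected with advice
  aniso <- voxel_volume(array(TRUE, c(5, 5, 5)), c(1, 1, 5))
  expect_error(skeletonize(aniso), "interpolate")

  # solid straight tube -> single centreline within 1 voxel of the axis
  dims <- c(60, 30, 30)
  g <- tube_graph(c(0, 15, 15), c(60, 15, 15), radius = 4)
  spec <- synthetic_spec(volume_extent = dims, voxel_spacing = c(1, 1, 1),
                         n_seed_vessels = 0, noise_sd = 0, psf_sigma = 0)
  mask <- rasterize_graph(list(graph = g), spec, channels = FALSE)$mask
  sk <- skeletonize(mask)
  expect_gt(nrow(sk$voxels), 40)
  dev <- abs(sweep(sk$voxels[, 2:3, drop = FALSE], 2, c(15.5, 15.5)))
  expect_lte(max(dev), 1)

  # torus -> exactly one cycle, one component
  d3 <- c(50, 50, 16)
  arr <- array(FALSE, d3)
  for (i in 1:50) for (j in 1:50) {
    rho <- sqrt((i - 25.5)^2 + (j - 25.5)^2)
    for (k in 1:16) arr[i, j, k] <- (rho - 15)^2 + (k - 8.5)^2 <= 12.25
  }
  tor <- voxel_volume(arr, c(1, 1, 1))
  gt <- build_graph(measure_radii(tor, skeletonize(tor)))
  expect_equal(graph_cycle_count(gt), 1)
  expect_equal(length(unique(graph_components(gt))), 1)
})

test_that("radius measurement matches analytic values and tapers", {
  dims <- c(60, 30, 30)
  g <- tube_graph(c(0, 15, 15), c(60, 15, 15), radius = 4)
  spec <- synthetic_spec(volume_extent = dims, voxel_spacing = c(1, 1, 1),
                         n_seed_vessels = 0, noise_sd = 0, psf_sigma = 0)
  mask <- rasterize_graph(list(graph = g), spec, channels = FALSE)$mask
  sk <- measure_radii(mask, skeletonize(mask))
  expect_true(all(abs(sk$radius_um - 4) <= 1))

  # skeleton voxel outside the mask is an error
  sk_bad <- sk
  sk_bad$voxels[1, ] <- c(1L, 1L, 1L)
  expect_error(measure_radii(mask, sk_bad), "outside")

  # tapering cone: radii decrease monotonically along x (within a voxel)
  cone <- array(FALSE, c(80, 40, 40))
  for (i in 1:80) {
    r <- 8 - 6 * (i - 1) / 79
    for (j in 1:40) for (k in 1:40)
      cone[i, j, k] <- (j - 20.5)^2 + (k - 20.5)^2 <= r^2
  }
  vc <- voxel_volume(cone, c(1, 1, 1))
  skc <- measure_radii(vc, skeletonize(vc))
  ord <- order(skc$voxels[, 1])
  rr <- skc$radius_um[ord]
  interior <- rr[5:(length(rr) - 5)]
  expect_true(all(diff(interior) <= 1 + 1e-9))
  expect_lt(interior[length(interior)], interior[1])
})

test_that("graph building collapses chains and merges close branch nodes", {
  # X shape drawn as skeleton voxels in a plane
  d <- c(21, 21, 3)
  vox <- NULL
  for (t in 0:20) vox <- rbind(vox, c(t + 1, t + 1, 2), c(t + 1, 21 - t, 2))
  vox <- unique(vox)
  sk <- structure(list(voxels = vox, radius_um = rep(1, nrow(vox)),
                       spacing = c(1, 1, 1), dim = d, origin = c(0, 0, 0)),
                  class = "skeleton")
  g <- build_graph(sk)
  expect_equal(sum(g$nodes$kind == "branch"), 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 4)
  expect_equal(nrow(g$segments), 4)

  # two branch nodes 6 um apart (< 10 um rule) merge into one
  np <- rbind(c(50, 50, 50), c(56, 50, 50),
              c(50, 90, 50), c(50, 10, 50), c(96, 90, 50), c(96, 10, 50))
  ed <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 5), c(2, 6))
  gm <- vasculomap:::.build_graph_from_edges(np, ed, radius = 2, step = 5)
  gc <- contract_short_internodes(gm, 10)
  expect_equal(sum(gc$nodes$kind == "branch"), 1)
  expect_equal(nrow(gc$segments), 4)

  # total graph length tracks the skeleton path length within 1%
  dims <- c(60, 30, 30)
  tg <- tube_graph(c(0, 15, 15), c(60, 15, 15), radius = 3)
  spec <- synthetic_spec(volume_extent = dims, voxel_spacing = c(1, 1, 1),
                         n_seed_vessels = 0, noise_sd = 0, psf_sigma = 0)
  mask <- rasterize_graph(list(graph = tg), spec, channels = FALSE)$mask
  skt <- measure_radii(mask, skeletonize(mask))
  gt <- build_graph(skt)
  # oracle: sum of consecutive voxel-step distances along the chain
  ord <- order(skt$voxels[, 1])
  steps <- diff(skt$voxels[ord, , drop = FALSE])
  oracle_len <- sum(sqrt(rowSums(steps^2)))
  expect_equal(graph_total_length(gt), oracle_len, tolerance = 0.01)
})

test_that("endpoint reconnection follows the greedy 10-um rule", {
  g8 <- reconnect_endpoints(fixture_gap_graph(8))
  expect_equal(length(unique(graph_components(g8))), 1)
  g12 <- reconnect_endpoints(fixture_gap_graph(12))
  expect_equal(length(unique(graph_components(g12))), 2)

  # three endpoints mutually within 10 um: only the nearest pair joins
  np <- rbind(c(50, 50, 50), c(150, 50, 50),
              c(156, 50, 50), c(256, 50, 50),
              c(153, 58, 50), c(153, 158, 50))
  ed <- rbind(c(1, 2), c(3, 4), c(5, 6))
  g3 <- vasculomap:::.build_graph_from_edges(np, ed, radius = 2, step = 10)
  # pair distances: (2,3)=6, (2,5)=sqrt(9+64)=8.5, (3,5)=sqrt(9+64)=8.5
  gr <- reconnect_endpoints(g3, collapse = FALSE)
  expect_equal(length(unique(graph_components(gr))), 2)
  deg <- node_degrees(gr)
  expect_equal(unname(deg[c("2", "3")]), c(2, 2))  # nearest pair joined
  expect_equal(unname(deg["5"]), 1)                # third left alone

  # reconnection never increases the component count
  set.seed(9)
  for (trial in 1:5) {
    spec <- synthetic_spec(volume_extent = c(200, 200, 200),
                           voxel_spacing = c(1, 1, 1), n_seed_vessels = 4,
                           rng_seed = 100 + trial)
    g <- generate_vascular_graph(spec)$graph
    if (!nrow(g$segments)) next
    before <- length(unique(graph_components(g)))
    after <- length(unique(graph_components(reconnect_endpoints(g, 25))))
    expect_lte(after, before)
  }
})

test_that("spur pruning removes sub-50-um furs shortest-first to a fixed point", {
  g <- fixture_spur_graph(c(30, 49, 51))
  gp <- prune_spurs(g)
  lens <- sort(round(gp$segments$length_um))
  # 30 and 49 gone; 51 retained; backbone split around its node
  expect_true(51 %in% lens)
  expect_false(any(c(30, 49) %in% lens))
  expect_equal(sum(gp$segments$length_um), 300 + 51)

  # isolated 40-um segment is its own fur
  iso <- tube_graph(c(10, 50, 50), c(50, 50, 50), radius = 2)
  expect_equal(nrow(prune_spurs(iso)$segments), 0)
  expect_equal(nrow(prune_spurs(iso, keep_isolated = TRUE)$segments), 1)

  # idempotence and the fixed-point property: no terminal segment < 50
  set.seed(13)
  for (trial in 1:5) {
    spec <- synthetic_spec(volume_extent = c(250, 250, 250),
                           voxel_spacing = c(1, 1, 1), n_seed_vessels = 5,
                           branch_probability = 0.02, rng_seed = 200 + trial)
    g <- generate_vascular_graph(spec)$graph
    p1 <- prune_spurs(g)
    p2 <- prune_spurs(p1)
    expect_equal(p1$segments$length_um, p2$segments$length_um)
    if (nrow(p1$segments)) {
      deg <- node_degrees(p1)
      a <- as.character(p1$segments$node_a); b <- as.character(p1$segments$node_b)
      terminal <- deg[a] == 1 | deg[b] == 1
      expect_true(all(p1$segments$length_um[terminal] >= 50 - 1e-9))
      # pruning only ever removes length (retained segments may merge,
      # never shrink), so every retained length is at least the
      # shortest original and the total never grows
      expect_lte(graph_total_length(p1), graph_total_length(g) + 1e-9)
      expect_gte(min(p1$segments$length_um),
                 min(g$segments$length_um) - 1e-9)
    }
  }
})

test_that("connectivity QC computes um-per-node and applies the 250 rule", {
  g <- tube_graph(c(0, 50, 50), c(1000, 50, 50), radius = 3)
  qc <- qc_connectivity_filter(g)
  expect_true(qc$pass)
  expect_equal(qc$ratio, 500)

  # 20 fragments of 20 um: 40 nodes, 400 um -> ratio 10, fail
  np <- NULL
  for (i in 0:19) np <- rbind(np, c(i * 40 + 5, 10, 10), c(i * 40 + 25, 10, 10))
  ed <- cbind(seq(1, 39, 2), seq(2, 40, 2))
  frag <- vasculomap:::.build_graph_from_edges(np, ed, radius = 2, step = 10)
  qf <- qc_connectivity_filter(frag)
  expect_false(qf$pass)
  expect_equal(qf$ratio, 10)

  # empty graph: no nodes -> fail with undefined ratio
  q0 <- qc_connectivity_filter(vessel_graph())
  expect_false(q0$pass)
  expect_true(is.na(q0$ratio))

  # ROI-restricted ratio equals a brute-force recount
  set.seed(31)
  spec <- synthetic_spec(volume_extent = c(190, 190, 190),
                         voxel_spacing = c(1, 1, 1), n_seed_vessels = 4,
                         rng_seed = 77)
  g <- generate_vascular_graph(spec)$graph
  roi <- voxel_volume(array(FALSE, c(20, 20, 20)), c(10, 10, 10))
  roi$data[1:10, , ] <- TRUE   # x < 100 um
  qr <- qc_connectivity_filter(g, roi)
  len_in <- 0
  for (i in seq_len(nrow(g$segments))) {
    p <- g$polylines[[i]]
    for (j in seq_len(nrow(p) - 1)) {
      mids <- outer(seq(0.005, 0.995, by = 0.01), p[j + 1, ] - p[j, ]) +
        rep(1, 100) %o% p[j, ]
      dl <- sqrt(sum((p[j + 1, ] - p[j, ])^2)) / 100
      len_in <- len_in + sum(mids[, 1] < 100) * dl
    }
  }
  expect_equal(qr$length_um, len_in, tolerance = 0.02)
  expect_equal(qr$n_nodes, sum(g$nodes$x < 100))
})

test_that("noise-free network tracing recovers ground truth (quick check)", {
  spec <- recovery_spec(6)
  truth <- generate_vascular_graph(spec)
  mask <- rasterize_graph(truth, spec, channels = FALSE)$mask
  g <- trace_vessels(mask)
  expect_equal(sum(g$nodes$kind == "branch"),
               sum(truth$graph$nodes$kind == "branch"))
  expect_equal(graph_total_length(g), graph_total_length(truth$graph),
               tolerance = 0.05)
  expect_equal(length_weighted_radius(g), length_weighted_radius(truth$graph),
               tolerance = 0.15)
})
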