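test_that("control-volume clipping cuts segments at the faces", {
  ctr <- c(200, 200, 200)
  # fully inside: no boundary nodes
  gin <- tube_graph(c(100, 200, 200), c(300, 200, 200), radius = 3)
  cin <- clip_to_control_volume(gin, ctr, 400)
  expect_equal(attr(cin, "n_boundary_nodes"), 0)
  # spanning tube: exactly two boundary nodes on opposite faces
  gsp <- tube_graph(c(-100, 200, 200), c(500, 200, 200), radius = 3)
  csp <- clip_to_control_volume(gsp, ctr, 400)
  expect_equal(attr(csp, "n_boundary_nodes"), 2)
  bx <- csp$nodes$x[csp$nodes$kind == "boundary"]
  expect_setequal(round(bx), c(0, 400))
  # clipped length equals the analytic line-box intersection
  set.seed(5)
  for (trial in 1:10) {
    a <- stats::runif(3, -200, 600); b <- stats::runif(3, -200, 600)
    g <- tube_graph(a, b, radius = 2, step = 37)
    gc <- clip_to_control_volume(g, ctr, 400)
    # oracle: dense sampling of the segment inside the box
    t <- seq(0.0005, 0.9995, by = 0.001)
    pts <- outer(t, b - a) + rep(1, length(t)) %o% a
    inside <- apply(pts, 1, function(p) all(p >= 0) && all(p <= 400))
    analytic <- sum(inside) / length(t) * sqrt(sum((b - a)^2))
    expect_equal(graph_total_length(gc), analytic, tolerance = 0.01)
  }
})

test_that("network flow solves Hagen-Poiseuille with conservation", {
  ctr <- c(200, 200, 200)
  # no boundary nodes -> zero flux everywhere
  gin <- clip_to_control_volume(tube_graph(c(100, 200, 200), c(300, 200, 200)),
                                ctr, 400)
  sol0 <- solve_network_flow(gin, c(1, 0, 0))
  expect_true(all(sol0$segment_fluxes == 0))

  # single spanning tube: flux = pi r^4 / 8 per unit gradient
  for (r in c(2, 3)) {
    gt <- clip_to_control_volume(fixture_axial_tube(r), ctr, 400)
    sol <- solve_network_flow(gt, c(1, 0, 0))
    expect_equal(max(abs(sol$segment_fluxes)), pi * r^4 / 8, tolerance = 1e-9)
  }

  # two identical parallel tubes: total flux exactly doubles
  g2 <- fixture_axial_tube(2)
  g2b <- fixture_axial_tube(2)
  g2b$polylines <- lapply(g2b$polylines, function(p) {
    p[, 2] <- p[, 2] + 100; p
  })
  g2b$nodes$y <- g2b$nodes$y + 100
  g2b$nodes$id <- g2b$nodes$id + 10
  g2b$segments$node_a <- g2b$segments$node_a + 10
  g2b$segments$node_b <- g2b$segments$node_b + 10
  g2b$segments$id <- g2b$segments$id + 10
  both <- vessel_graph(rbind(g2$nodes, g2b$nodes),
                       rbind(g2$segments, g2b$segments),
                       c(g2$polylines, g2b$polylines),
                       c(g2$radii, g2b$radii))
  kb <- compute_flow_tensor(both, ctr, 400)
  k1 <- compute_flow_tensor(g2, ctr, 400)
  expect_equal(kb$k[1, 1], 2 * k1$k[1, 1], tolerance = 1e-12)

  # interior conservation residual on a branched lattice
  lat <- fixture_lattice_graph(n = 3, pitch = 100, radius = 3)
  lc <- clip_to_control_volume(lat, c(150, 150, 150), 200)
  sol <- solve_network_flow(lc, c(0.6, 0.5, sqrt(1 - 0.61)))
  expect_lt(sol$residual, 1e-8 * mean(abs(sol$segment_fluxes[
    sol$segment_fluxes != 0])))
})

test_that("flow tensors match closed forms and superposition", {
  ctr <- c(200, 200, 200)
  expect_equal(compute_flow_tensor(vessel_graph(), ctr, 400)$k, matrix(0, 3, 3))
  for (r in c(2, 3, 5)) {
    ft <- compute_flow_tensor(fixture_axial_tube(r), ctr, 400)
    expect_equal(ft$k[1, 1], pi * r^4 / 8, tolerance = 0.005)
    expect_lt(max(abs(ft$k[-1])), 1e-9 * ft$k[1, 1])
  }
  # orthogonal tube triple: diagonal tensor with equal entries
  triple <- NULL
  gx <- fixture_axial_tube(3, axis = 1); gy <- fixture_axial_tube(3, axis = 2)
  gz <- fixture_axial_tube(3, axis = 3)
  # keep tubes from intersecting: offset each off the centre line
  shift <- function(g, dy, dz) {
    g$polylines <- lapply(g$polylines, function(p) {
      p[, 2] <- p[, 2] + dy; p[, 3] <- p[, 3] + dz; p })
    g$nodes$y <- g$nodes$y + dy; g$nodes$z <- g$nodes$z + dz
    g
  }
  gy <- shift(gy, 0, 60); gz <- shift(gz, 60, 0)
  relabel <- function(g, off) {
    g$nodes$id <- g$nodes$id + off
    g$segments$node_a <- g$segments$node_a + off
    g$segments$node_b <- g$segments$node_b + off
    g$segments$id <- g$segments$id + off
    g
  }
  gy <- relabel(gy, 10); gz <- relabel(gz, 20)
  gall <- vessel_graph(rbind(gx$nodes, gy$nodes, gz$nodes),
                       rbind(gx$segments, gy$segments, gz$segments),
                       c(gx$polylines, gy$polylines, gz$polylines),
                       c(gx$radii, gy$radii, gz$radii))
  kt <- compute_flow_tensor(gall, ctr, 400)$k
  expect_equal(diag(kt), rep(pi * 81 / 8, 3), tolerance = 1e-9)
  expect_lt(max(abs(kt - diag(diag(kt)))), 1e-9)
})

test_that("radius growth never decreases diagonal tensor entries", {
  lat <- fixture_lattice_graph(n = 3, pitch = 120, radius = 2.5,
                               origin = c(40, 40, 40))
  k0 <- compute_flow_tensor(lat, c(160, 160, 160), 240)$k
  set.seed(17)
  for (trial in 1:5) {
    g2 <- lat
    s <- sample(nrow(g2$segments), 1)
    g2$radii[[s]] <- g2$radii[[s]] + stats::runif(1, 0.5, 2)
    g2 <- vasculomap:::refresh_graph(g2)
    k1 <- compute_flow_tensor(g2, c(160, 160, 160), 240)$k
    expect_true(all(diag(k1) >= diag(k0) - 1e-9))
  }
})

test_that("isotropic lattice tensors are symmetric and near-diagonal", {
  lat <- fixture_lattice_graph(n = 4, pitch = 100, radius = 3,
                               origin = c(50, 50, 50))
  k <- compute_flow_tensor(lat, c(200, 200, 200), 300)$k
  expect_lt(norm(k - t(k), "F") / norm(k, "F"), 0.05)
  offdiag <- k - diag(diag(k))
  expect_lt(max(abs(offdiag)), 0.05 * mean(diag(k)))
})

test_that("flux is plane-independent for a spanning tube", {
  g <- fixture_axial_tube(3)
  gc <- clip_to_control_volume(g, c(200, 200, 200), 400)
  sol <- solve_network_flow(gc, c(1, 0, 0))
  fluxes <- vapply(c(100, 200, 300), function(x)
    vasculomap:::.plane_flux(gc, sol$segment_fluxes, 1, x), 0)
  expect_equal(fluxes[1], fluxes[2], tolerance = 1e-9)
  expect_equal(fluxes[2], fluxes[3], tolerance = 1e-9)
})

test_that("tensor projection onto cortical axes behaves geometrically", {
  pI <- project_tensor(diag(3), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(c(pI$k_P, pI$k_AP, pI$k_ML), c(1, 1, 1))
  expect_true(is.na(pI$dominant))

  ka <- diag(c(6.28, 0, 0))
  pa <- project_tensor(ka, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(pa$k_P, 6.28)
  expect_lt(pa$k_AP, 1e-12)
  expect_equal(pa$dominant, "P")

  expect_warning(project_tensor(ka, c(2, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 "unit")

  # joint rotation of tensor and axes leaves projections unchanged
  set.seed(3)
  for (trial in 1:5) {
    k <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    axes <- diag(3)
    p0 <- project_tensor(k, axes[, 1], axes[, 2], axes[, 3])
    kR <- Q %*% k %*% t(Q)
    pR <- project_tensor(kR, Q %*% axes[, 1], Q %*% axes[, 2], Q %*% axes[, 3])
    expect_equal(c(p0$k_P, p0$k_AP, p0$k_ML), c(pR$k_P, pR$k_AP, pR$k_ML),
                 tolerance = 1e-9)
  }
})

test_that("Fibonacci-sphere conductance matches spherical closed forms", {
  expect_equal(spherical_conductance(matrix(0, 3, 3)), 0)
  expect_equal(spherical_conductance(3 * diag(3)), 3, tolerance = 1e-12)
  for (a in c(1, 6.283, 40)) {
    got <- spherical_conductance(diag(c(a, 0, 0)))
    expect_equal(got, a / 2, tolerance = 0.005)
  }
  # determinism and unit norms
  d1 <- fibonacci_sphere(2000)
  d2 <- fibonacci_sphere(2000)
  expect_identical(d1, d2)
  expect_equal(rowSums(d1^2), rep(1, 2000), tolerance = 1e-12)
})
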