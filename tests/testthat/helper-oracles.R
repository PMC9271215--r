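# Independent oracles and small builders shared across the suite.

# Brute-force tube occupancy: voxel centres within `radius` of the
# segment [a, b], on a grid of `dims` voxels at `spacing` um.
oracle_tube_mask <- function(a, b, radius, dims, spacing) {
  out <- array(FALSE, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    p <- (c(i, j, k) - 0.5) * spacing
    u <- b - a
    t <- sum((p - a) * u) / sum(u * u)
    t <- min(max(t, 0), 1)
    d <- sqrt(sum((p - (a + t * u))^2))
    out[i, j, k] <- d <= radius
  }
  out
}

# Textbook Pearson R and two-sided p via sums (independent of cor.test)
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, p = p)
}

# Optimal one-to-one matching count within radius (maximum bipartite
# matching, igraph) -- oracle for the greedy matcher.
oracle_optimal_matches <- function(det, truth, radius) {
  nd <- nrow(det); nt <- nrow(truth)
  if (nd == 0 || nt == 0) return(0L)
  edges <- NULL
  for (i in seq_len(nd)) for (j in seq_len(nt)) {
    d <- sqrt(sum((as.numeric(det[i, c("x_um", "y_um")]) -
                     as.numeric(truth[j, c("x_um", "y_um")]))^2))
    if (d <= radius) edges <- rbind(edges, c(i, nd + j))
  }
  if (is.null(edges)) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nd), rep(TRUE, nt)),
    edges = as.vector(t(edges)))
  igraph::max_bipartite_match(g)$matching_size
}

# Block annotation: n regions as consecutive slabs along x.
block_annotation <- function(n_regions, block_vox = c(10, 10, 10),
                             spacing = 10) {
  d <- c(block_vox[1] * n_regions, block_vox[2], block_vox[3])
  lab <- array(0L, d)
  for (r in seq_len(n_regions))
    lab[(r - 1) * block_vox[1] + seq_len(block_vox[1]), , ] <- r
  voxel_volume(lab, rep(spacing, 3))
}

# Straight-tube graph between two points
tube_graph <- function(a, b, radius = 3, step = 20) {
  vasculomap:::.build_graph_from_edges(rbind(a, b), cbind(1, 2),
                                       radius = radius, step = step)
}

# The stated-world generator for tracing-recovery experiments:
# segments >= 60 um, radii >= 2 um, centreline separation > 12 um,
# noise-free, at the 1 um isotropic working resolution.
recovery_spec <- function(seed) {
  synthetic_spec(volume_extent = c(250, 250, 250), voxel_spacing = c(1, 1, 1),
                 n_seed_vessels = 5, radius_range = c(2, 4),
                 tortuosity = 0.1, branch_probability = 0.02,
                 noise_sd = 0, psf_sigma = 0, rng_seed = seed,
                 step_um = 5, max_walk_um = 250,
                 min_segment_um = 60, min_separation_um = 16)
}

length_weighted_radius <- function(g) {
  sum(g$segments$length_um * g$segments$mean_radius_um) /
    sum(g$segments$length_um)
}
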