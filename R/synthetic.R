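#' Specification for synthetic vascular volumes
#'
#' Bundles the parameters of the synthetic ground-truth generator: the
#' stated world is a 400 x 400 x 400 um tissue block imaged at
#' 1 x 1 x 5 um (the anisotropic sampling of serial two-photon
#' tomography), with bright tube-filling signal over a dim
#' autofluorescent background shared by both channels.
#'
#' @param volume_extent um per axis (ML, DV, AP), all > 0.
#' @param voxel_spacing um per axis; anisotropic allowed.
#' @param n_seed_vessels number of seeded vessel trees.
#' @param radius_range um, (min, max) of per-segment radii; min > 0.
#' @param tortuosity dimensionless >= 0; SD of the per-step direction
#'   perturbation (0 = straight vessels).
#' @param branch_probability per-um branching rate of a growing tip.
#' @param signal_level tube intensity added to the signal channel.
#' @param background_level mean background intensity in both channels.
#' @param noise_sd additive Gaussian noise SD (both channels).
#' @param psf_sigma um, isotropic Gaussian blur emulating the PSF.
#' @param rng_seed integer seed; every random draw derives from it.
#' @param step_um um, growth step of the vessel walk.
#' @param max_walk_um um, maximum arc length of one unbranched walk.
#' @param min_segment_um um, minimum arc length between graph nodes
#'   (0 disables the constraint).
#' @param min_separation_um um, minimum centreline gap enforced between
#'   non-adjacent vessels (0 disables the check).
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(volume_extent = c(400, 400, 400),
                           voxel_spacing = c(1, 1, 5),
                           n_seed_vessels = 8,
                           radius_range = c(2, 6),
                           tortuosity = 0.15,
                           branch_probability = 0.005,
                           signal_level = 200,
                           background_level = 20,
                           noise_sd = 5,
                           psf_sigma = 1,
                           rng_seed = 1L,
                           step_um = 5,
                           max_walk_um = 200,
                           min_segment_um = 0,
                           min_separation_um = 0) {
  spec <- list(volume_extent = rep(as.numeric(volume_extent), length.out = 3),
               voxel_spacing = rep(as.numeric(voxel_spacing), length.out = 3),
               n_seed_vessels = as.integer(n_seed_vessels),
               radius_range = as.numeric(radius_range),
               tortuosity = as.numeric(tortuosity),
               branch_probability = as.numeric(branch_probability),
               signal_level = signal_level, background_level = background_level,
               noise_sd = noise_sd, psf_sigma = psf_sigma,
               rng_seed = as.integer(rng_seed), step_um = step_um,
               max_walk_um = max_walk_um, min_segment_um = min_segment_um,
               min_separation_um = min_separation_um)
  with(spec, {
    if (any(volume_extent <= 0) || any(voxel_spacing <= 0))
      stop("extents and spacings must be positive")
    if (radius_range[1] <= 0 || diff(radius_range) < 0)
      stop("radius_range must be positive and ordered")
    if (tortuosity < 0 || noise_sd < 0 || branch_probability < 0)
      stop("tortuosity, noise_sd and branch_probability must be >= 0")
  })
  structure(spec, class = "synthetic_spec")
}

# Evaluate `code` under a fixed seed without touching the caller's RNG.
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# random unit vector
.runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# rotate `dir` away from itself by angle `theta`; `axis` fixes the
# rotation plane (random when NULL)
.deflect <- function(dir, theta, axis = NULL) {
  a <- if (is.null(axis)) .runit() else axis
  perp <- a - sum(a * dir) * dir
  n <- sqrt(sum(perp^2))
  if (n < 1e-9) return(.deflect(dir, theta))
  perp <- perp / n
  cos(theta) * dir + sin(theta) * perp
}

#' Generate a ground-truth vascular graph
#'
#' Seeded random-walk vessel trees: each tip advances in steps of
#' \code{step_um}, its direction perturbed by a Gaussian of SD
#' \code{tortuosity} radians per step, and branches as a Bernoulli event
#' at rate \code{branch_probability} per um.  Radii are constant per
#' segment, drawn uniformly from \code{radius_range}.  Walks stop at the
#' volume boundary (clipped exactly to it), at \code{max_walk_um}, or
#' when \code{min_separation_um} would be violated.  Deterministic for a
#' fixed \code{rng_seed}.
#'
#' @param spec a \code{synthetic_spec}.
#' @return list with elements \code{graph} (a \code{vessel_graph}),
#'   \code{cells} (empty data.frame placeholder) and \code{spec}.
#' @export
generate_vascular_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ext <- spec$volume_extent
  rmax <- spec$radius_range[2]
  if (any(ext <= 2 * rmax + 2 * spec$step_um))
    stop("volume extent too small to place a vessel of radius ", rmax, " um")
  truth <- with_rng_seed(spec$rng_seed, .grow_forest(spec))
  list(graph = truth, cells = data.frame(), spec = spec)
}

.grow_forest <- function(spec) {
  ext <- spec$volume_extent
  margin <- spec$radius_range[2] + 1
  env <- new.env()
  env$points <- matrix(numeric(0), ncol = 3)   # all laid points
  env$pt_seg <- integer(0)                     # owning segment per point
  env$segs <- list()    # list of list(points, node_a, node_b)
  env$nodes <- list()   # list of list(pos, kind)
  env$adjacent <- list()  # per segment: ids exempt from separation test

  add_node <- function(pos, kind) {
    env$nodes[[length(env$nodes) + 1]] <- list(pos = pos, kind = kind)
    length(env$nodes)
  }
  sep_ok <- function(p, sid_self, exempt) {
    if (spec$min_separation_um <= 0 || nrow(env$points) == 0) return(TRUE)
    d2 <- rowSums(sweep(env$points, 2, p)^2)
    bad <- d2 < spec$min_separation_um^2 & !(env$pt_seg %in% c(sid_self, exempt))
    !any(bad)
  }

  if (spec$n_seed_vessels == 0) return(vessel_graph())

  # queue of tips: list(pos, dir, node_from, depth, exempt segment ids)
  queue <- list()
  margin <- max(margin, min(20, min(ext) / 4))
  for (i in seq_len(spec$n_seed_vessels)) {
    for (try in 1:25) {
      pos <- margin + stats::runif(3) * (ext - 2 * margin)
      if (sep_ok(pos, -1L, integer(0))) break
    }
    nid <- add_node(pos, "endpoint")
    queue[[length(queue) + 1]] <-
      list(pos = pos, dir = .runit(), node_from = nid, depth = 0L,
           exempt = integer(0))
  }

  p_branch <- min(1, spec$branch_probability * spec$step_um)
  while (length(queue)) {
    tip <- queue[[1]]; queue <- queue[-1]
    sid <- length(env$segs) + 1L
    # segments meeting this walk at its origin node (parent and
    # siblings) are exempt from the separation test near the junction
    if (length(env$segs)) {
      adj <- which(vapply(env$segs, function(s)
        !is.null(s) && (s$node_a == tip$node_from || s$node_b == tip$node_from),
        TRUE))
      tip$exempt <- unique(c(tip$exempt, adj))
    }
    pts <- matrix(tip$pos, ncol = 3)
    dir <- tip$dir
    arc <- 0
    end_node <- NA_integer_
    child_tips <- list()
    repeat {
      if (spec$tortuosity > 0)
        dir <- .deflect(dir, abs(stats::rnorm(1, 0, spec$tortuosity)))
      nxt <- pts[nrow(pts), ] + spec$step_um * dir
      if (any(nxt < 0) || any(nxt > ext)) {
        # clip exactly to the boundary and stop
        cur <- pts[nrow(pts), ]
        tt <- 1
        for (ax in 1:3) {
          if (nxt[ax] < 0) tt <- min(tt, (0 - cur[ax]) / (nxt[ax] - cur[ax]))
          if (nxt[ax] > ext[ax]) tt <- min(tt, (ext[ax] - cur[ax]) / (nxt[ax] - cur[ax]))
        }
        hit <- cur + tt * (nxt - cur)
        if (tt > 1e-6) pts <- rbind(pts, hit)
        end_node <- add_node(pts[nrow(pts), ], "endpoint")
        break
      }
      if (!sep_ok(nxt, sid, tip$exempt)) {
        if (arc < max(spec$min_segment_um, spec$step_um) && tip$depth > 0) {
          # too short to keep: abort this walk entirely
          pts <- NULL
        } else end_node <- add_node(pts[nrow(pts), ], "endpoint")
        break
      }
      pts <- rbind(pts, nxt)
      arc <- arc + spec$step_um
      if (arc >= spec$max_walk_um) {
        end_node <- add_node(nxt, "endpoint")
        break
      }
      branch_allowed <- arc >= spec$min_segment_um && tip$depth < 4L
      if (branch_allowed && stats::runif(1) < p_branch) {
        end_node <- add_node(nxt, "branch")
        th1 <- stats::runif(1, pi / 6, pi / 3)
        th2 <- stats::runif(1, pi / 6, pi / 3)
        # children deflect to opposite sides of a common plane so their
        # tubes separate promptly beyond the junction
        ax <- .runit()
        child_tips <- list(
          list(pos = nxt, dir = .deflect(dir, th1, ax), node_from = end_node,
               depth = tip$depth + 1L, exempt = sid),
          list(pos = nxt, dir = .deflect(dir, -th2, ax), node_from = end_node,
               depth = tip$depth + 1L, exempt = sid))
        break
      }
    }
    if (is.null(pts) || nrow(pts) < 2) next
    # under the minimum-segment regime, walks cut short (boundary or
    # separation) are dropped so every ground-truth segment honours it
    if (spec$min_segment_um > 0 && !length(child_tips) &&
        polyline_length(pts) < spec$min_segment_um) next
    env$segs[[sid]] <- list(points = pts, node_a = tip$node_from,
                            node_b = end_node)
    env$points <- rbind(env$points, pts)
    env$pt_seg <- c(env$pt_seg, rep(sid, nrow(pts)))
    for (ct in child_tips) {
      ct$exempt <- c(ct$exempt, sid)
      queue[[length(queue) + 1]] <- ct
    }
  }

  if (!length(env$segs)) return(vessel_graph())
  nodes <- data.frame(
    id = seq_along(env$nodes),
    x = vapply(env$nodes, function(n) n$pos[1], 0),
    y = vapply(env$nodes, function(n) n$pos[2], 0),
    z = vapply(env$nodes, function(n) n$pos[3], 0),
    kind = vapply(env$nodes, function(n) n$kind, ""))
  segments <- data.frame(
    id = seq_along(env$segs),
    node_a = vapply(env$segs, function(s) s$node_a, 0L),
    node_b = vapply(env$segs, function(s) s$node_b, 0L))
  polylines <- lapply(env$segs, function(s) unname(s$points))
  radii <- lapply(env$segs, function(s)
    rep(stats::runif(1, spec$radius_range[1], spec$radius_range[2]),
        nrow(s$points)))
  g <- vessel_graph(nodes, segments, polylines, radii)
  # aborted children can leave degree-2 "branch" nodes: canonicalise
  collapse_interior_nodes(g)
}

#' Rasterize a ground-truth graph into a two-channel volume
#'
#' The signal channel is the union of tubes (per-segment radius) at
#' \code{signal_level} over the shared background; the background
#' channel carries the same low-frequency autofluorescent structure and
#' noise but no tubes.  Both channels are blurred by \code{psf_sigma}.
#'
#' @param truth output of \code{\link{generate_vascular_graph}} (or any
#'   list with a \code{graph} element).
#' @param spec a \code{synthetic_spec}.
#' @param channels set FALSE to skip channel synthesis and return only
#'   the noise-free tube mask (fast path for recovery experiments).
#' @return list of class \code{two_channel_volume}: \code{signal} and
#'   \code{background} (both \code{voxel_volume}), \code{mask} (the
#'   noise-free, blur-free tube occupancy), and
#'   \code{subvoxel_warning} (TRUE when some tube radius is below half
#'   the largest voxel spacing).
#' @export
rasterize_graph <- function(truth, spec, channels = TRUE) {
  g <- truth$graph
  ext <- spec$volume_extent
  sp <- spec$voxel_spacing
  dims <- as.integer(round(ext / sp))
  segs <- .graph_to_subsegments(g)
  if (nrow(segs)) {
    if (any(segs[, 1:3] < -1e-6) || any(sweep(segs[, 1:3], 2, ext) > 1e-6) ||
        any(segs[, 4:6] < -1e-6) || any(sweep(segs[, 4:6], 2, ext) > 1e-6))
      stop("graph coordinates outside the volume extent")
  }
  mask <- if (nrow(segs))
    .cpp_rasterize_tubes(segs, dims, sp)
  else array(FALSE, dims)
  subvoxel <- nrow(segs) > 0 && any(segs[, 7] < max(sp) / 2)
  if (!channels)
    return(structure(list(
      signal = NULL, background = NULL,
      mask = voxel_volume(array(as.logical(mask), dims), sp),
      subvoxel_warning = subvoxel), class = "two_channel_volume"))

  out <- with_rng_seed(spec$rng_seed + 1L, {
    # shared low-frequency autofluorescent structure, synthesised on a
    # coarse grid (~25 um correlation scale) and upsampled
    lowf <- .coarse_noise(dims, sp, scale_um = 25)
    lowf <- lowf / max(1e-12, stats::sd(lowf)) * 0.25 * spec$background_level
    sig <- spec$background_level + lowf + spec$signal_level * mask
    bg <- spec$background_level + lowf
    if (spec$psf_sigma > 0) {
      sig <- gaussian_smooth3(sig, spec$psf_sigma / sp)
      bg <- gaussian_smooth3(bg, spec$psf_sigma / sp)
    }
    if (spec$noise_sd > 0) {
      sig <- sig + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
      bg <- bg + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
    }
    list(sig = sig, bg = bg)
  })
  structure(list(
    signal = voxel_volume(out$sig, sp),
    background = voxel_volume(out$bg, sp),
    mask = voxel_volume(array(as.logical(mask), dims), sp),
    subvoxel_warning = subvoxel), class = "two_channel_volume")
}

# Smooth low-frequency field: white noise on a coarse grid (one cell
# per `scale_um`), Gaussian-smoothed there, trilinearly upsampled.
.coarse_noise <- function(dims, sp, scale_um = 25) {
  cd <- pmax(2L, as.integer(ceiling(dims * sp / scale_um)) + 2L)
  cg <- array(stats::rnorm(prod(cd)), cd)
  cg <- gaussian_smooth3(cg, 1)
  # trilinear upsample onto the fine grid
  ax <- lapply(1:3, function(a) {
    t <- ((seq_len(dims[a]) - 0.5) * sp[a]) / scale_um + 1
    t <- pmin(pmax(t, 1), cd[a] - 1e-9)
    list(i0 = floor(t), f = t - floor(t))
  })
  i0 <- ax[[1]]$i0; fx <- ax[[1]]$f
  j0 <- ax[[2]]$i0; fy <- ax[[2]]$f
  k0 <- ax[[3]]$i0; fz <- ax[[3]]$f
  out <- array(0, dims)
  for (c in 0:7) {
    dx <- c %% 2; dy <- (c %/% 2) %% 2; dz <- c %/% 4
    wx <- if (dx) fx else 1 - fx
    wy <- if (dy) fy else 1 - fy
    wz <- if (dz) fz else 1 - fz
    sub <- cg[pmin(i0 + dx, cd[1]), pmin(j0 + dy, cd[2]),
              pmin(k0 + dz, cd[3]), drop = FALSE]
    w <- outer(outer(wx, wy), wz)
    out <- out + array(w, dims) * array(sub, dims)
  }
  out
}

# flatten graph polylines to (x1,y1,z1,x2,y2,z2,r) sub-segment rows
.graph_to_subsegments <- function(g) {
  rows <- list()
  for (i in seq_len(nrow(g$segments))) {
    p <- g$polylines[[i]]
    r <- g$radii[[i]]
    if (nrow(p) < 2) next
    n <- nrow(p)
    rr <- (r[-n] + r[-1]) / 2
    rows[[length(rows) + 1]] <-
      cbind(p[-n, , drop = FALSE], p[-1, , drop = FALSE], rr)
  }
  if (!length(rows)) return(matrix(numeric(0), ncol = 7))
  do.call(rbind, rows)
}

#' Layered cortical phantom
#'
#' Builds a labelled annotation volume with stacked (slab) or concentric
#' (half-cylinder) cortical layers over a non-cortex background (label
#' 0).  Layer labels are 1..n from the outer (layer-1) surface inward;
#' the innermost layer stands for layer 6b.
#'
#' @param shape \code{"slab"} or \code{"half_cylinder"}.
#' @param layer_fractions fractions of cortical thickness per layer,
#'   outermost first; must sum to 1 and have length >= 2.
#' @param extent um per axis.
#' @param spacing um per axis (scalar or length 3).
#' @param inner_radius um, half-cylinder only: radius of the layer-6b
#'   (inner) surface; the outer radius fills the DV extent minus margin.
#' @return integer \code{voxel_volume} with a \code{layers} attribute
#'   (data.frame: label, name, fraction) and, for the half-cylinder,
#'   \code{axis_center} / \code{outer_radius} / \code{inner_radius}
#'   attributes (um).
#' @export
generate_cortex_phantom <- function(shape = c("half_cylinder", "slab"),
                                    layer_fractions = c(0.1, 0.15, 0.2, 0.25, 0.2, 0.1),
                                    extent = c(400, 300, 200),
                                    spacing = 4,
                                    inner_radius = NULL) {
  shape <- match.arg(shape)
  if (length(layer_fractions) < 2)
    stop("at least 2 layers required (layer 1 and layer 6b)")
  if (abs(sum(layer_fractions) - 1) > 1e-8)
    stop("layer_fractions must sum to 1")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  extent <- rep(as.numeric(extent), length.out = 3)
  dims <- as.integer(round(extent / spacing))
  nlay <- length(layer_fractions)
  cum <- cumsum(c(0, layer_fractions))
  lab <- array(0L, dims)
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2]

  if (shape == "slab") {
    # stacked along DV; layer 1 at the high-DV (outer) side, background
    # margin above and below
    marg <- 3 * spacing[2]
    thick <- extent[2] - 2 * marg
    for (j in seq_len(dims[2])) {
      depth <- (extent[2] - marg) - cy[j]       # 0 at outer surface
      if (depth < 0 || depth > thick) next
      f <- depth / thick
      li <- findInterval(f, cum, rightmost.closed = TRUE)
      lab[, j, ] <- as.integer(min(max(li, 1L), nlay))
    }
    attrs <- list(thickness = thick, outer_dv = extent[2] - marg)
  } else {
    # half-cylinder: axis along AP at (ML centre, DV base), dome upward
    R <- min(extent[2] - 3 * spacing[2], extent[1] / 2 - 3 * spacing[1])
    r0 <- if (is.null(inner_radius)) 0.4 * R else inner_radius
    if (r0 <= 0 || r0 >= R) stop("inner_radius must lie in (0, outer radius)")
    ctr <- c(extent[1] / 2, 0)
    rad2 <- outer((cx - ctr[1])^2, (cy - ctr[2])^2, `+`)
    rho <- sqrt(rad2)
    f <- (R - rho) / (R - r0)                   # 0 at outer, 1 at inner
    li <- matrix(findInterval(f, cum, rightmost.closed = TRUE), dims[1], dims[2])
    li[f < 0 | f > 1] <- 0L
    li[li > nlay] <- nlay
    for (k in seq_len(dims[3])) lab[, , k] <- li
    attrs <- list(axis_center = ctr, outer_radius = R, inner_radius = r0)
  }
  vol <- voxel_volume(lab, spacing)
  attr(vol, "layers") <- data.frame(
    label = seq_len(nlay),
    name = c("layer1", paste0("layer", seq_len(max(0, nlay - 2)) + 1), "layer6b")[seq_len(nlay)],
    fraction = layer_fractions)
  for (nm in names(attrs)) attr(vol, nm) <- attrs[[nm]]
  attr(vol, "shape") <- shape
  vol
}

#' Homogeneous Poisson cell field per annotation region
#'
#' @param density_by_region named numeric vector, cells/mm^3 per region
#'   label (names are labels as character).
#' @param annotation labelled \code{voxel_volume}.
#' @param rng_seed integer seed.
#' @param class class label attached to all generated points.
#' @return data.frame \code{x_um, y_um, z_um, region, class}.
#' @export
generate_cell_field <- function(density_by_region, annotation, rng_seed = 1L,
                                class = "cell") {
  stopifnot(inherits(annotation, "voxel_volume"))
  if (any(density_by_region < 0)) stop("densities must be >= 0")
  labs <- annotation$data
  vox_mm3 <- prod(annotation$spacing) / 1e9
  with_rng_seed(rng_seed, {
    out <- list()
    for (rn in names(density_by_region)) {
      rid <- as.integer(rn)
      vox <- which(labs == rid)
      if (!length(vox))
        stop("region ", rn, " absent from annotation")
      d <- density_by_region[[rn]]
      if (d == 0) next
      vol_mm3 <- length(vox) * vox_mm3
      n <- stats::rpois(1, d * vol_mm3)
      if (n == 0) next
      pick <- vox[sample.int(length(vox), n, replace = TRUE)]
      ijk <- arrayInd(pick, dim(labs))
      jitter <- matrix(stats::runif(3 * n), ncol = 3)
      xyz <- sweep((ijk - 1 + jitter), 2, annotation$spacing, `*`)
      xyz <- sweep(xyz, 2, annotation$origin, `+`)
      out[[length(out) + 1]] <- data.frame(
        x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
        region = rid, class = class)
    }
    if (!length(out))
      return(data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                        region = integer(), class = character()))
    do.call(rbind, out)
  })
}

# --- canonical fixtures ----------------------------------------------------

#' Canonical test fixtures
#'
#' Deterministic small graphs and phantoms used across the test suite:
#' a backbone with spurs of 30, 49 and 51 um; collinear segment pairs
#' with endpoint gaps of 8 and 12 um; single axial tubes of radius 2, 3
#' and 5 um spanning a 400^3 um cube; a 3D lattice network; a
#' half-cylinder cortex phantom.
#'
#' @name fixtures
NULL

# straight segment helper
.seg_points <- function(a, b, step = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  L <- sqrt(sum((b - a)^2))
  n <- max(2L, as.integer(ceiling(L / step)) + 1L)
  t <- seq(0, 1, length.out = n)
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
        a[3] + t * (b[3] - a[3]))
}

.build_graph_from_edges <- function(node_pos, edges, radius = 3, step = 20) {
  nodes <- data.frame(id = seq_len(nrow(node_pos)), x = node_pos[, 1],
                      y = node_pos[, 2], z = node_pos[, 3], kind = "interior")
  segments <- data.frame(id = seq_len(nrow(edges)),
                         node_a = edges[, 1], node_b = edges[, 2])
  radius <- rep(radius, length.out = nrow(edges))
  polylines <- lapply(seq_len(nrow(edges)), function(i)
    .seg_points(node_pos[edges[i, 1], ], node_pos[edges[i, 2], ], step))
  radii <- lapply(seq_len(nrow(edges)), function(i)
    rep(radius[i], nrow(polylines[[i]])))
  vessel_graph(nodes, segments, polylines, radii)
}

#' @rdname fixtures
#' @param spur_lengths um, spur lengths attached to the backbone.
#' @return \code{fixture_spur_graph}: a \code{vessel_graph} with a
#'   300 um backbone and perpendicular spurs.
#' @export
fixture_spur_graph <- function(spur_lengths = c(30, 49, 51)) {
  y0 <- 100
  xs <- 80 + seq_along(spur_lengths) * 60
  node_pos <- rbind(c(20, y0, 50), c(320, y0, 50))
  for (i in seq_along(spur_lengths))
    node_pos <- rbind(node_pos, c(xs[i], y0, 50),
                      c(xs[i], y0 + spur_lengths[i], 50))
  # backbone chain through the spur attachment nodes, then the spurs
  chain <- c(1, seq(3, 1 + 2 * length(spur_lengths), by = 2), 2)
  edges <- cbind(chain[-length(chain)], chain[-1])
  for (i in seq_along(spur_lengths))
    edges <- rbind(edges, c(2 * i + 1, 2 * i + 2))
  .build_graph_from_edges(node_pos, edges, radius = 3, step = 10)
}

#' @rdname fixtures
#' @param gap um, endpoint gap between the two collinear segments.
#' @return \code{fixture_gap_graph}: two collinear 100 um segments
#'   separated by \code{gap} um.
#' @export
fixture_gap_graph <- function(gap = 8) {
  node_pos <- rbind(c(10, 50, 50), c(110, 50, 50),
                    c(110 + gap, 50, 50), c(210 + gap, 50, 50))
  edges <- rbind(c(1, 2), c(3, 4))
  .build_graph_from_edges(node_pos, edges, radius = 3, step = 10)
}

#' @rdname fixtures
#' @param radius um tube radius.
#' @param axis 1, 2 or 3: the axis the tube runs along.
#' @param size um cube edge length.
#' @return \code{fixture_axial_tube}: one straight tube through the cube
#'   centre spanning the full extent along \code{axis}.
#' @export
fixture_axial_tube <- function(radius = 2, axis = 1, size = 400) {
  a <- rep(size / 2, 3); b <- a
  a[axis] <- 0; b[axis] <- size
  .build_graph_from_edges(rbind(a, b), cbind(1, 2), radius = radius, step = 20)
}

#' @rdname fixtures
#' @param n nodes per axis of the lattice.
#' @param pitch um lattice pitch.
#' @param origin um corner offset of the lattice.
#' @return \code{fixture_lattice_graph}: isotropic 3D lattice with
#'   \code{n^2 (n-1)} edges along each axis.
#' @export
fixture_lattice_graph <- function(n = 3, pitch = 100, radius = 3,
                                  origin = c(50, 50, 50)) {
  idx <- as.matrix(expand.grid(i = 1:n, j = 1:n, k = 1:n))
  node_pos <- sweep((idx - 1) * pitch, 2, origin, `+`)
  lin <- function(i, j, k) (k - 1) * n * n + (j - 1) * n + i
  edges <- NULL
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    if (i < n) edges <- rbind(edges, c(lin(i, j, k), lin(i + 1, j, k)))
    if (j < n) edges <- rbind(edges, c(lin(i, j, k), lin(i, j + 1, k)))
    if (k < n) edges <- rbind(edges, c(lin(i, j, k), lin(i, j, k + 1)))
  }
  .build_graph_from_edges(node_pos, edges, radius = radius, step = 25)
}

#' Write the canonical fixture suite to a directory
#'
#' Writes the spur, gap, axial-tube and lattice fixtures as graph file
#' sets, the half-cylinder phantom as ASCII NRRD, and a
#' \code{manifest.json} listing every file with its ground-truth
#' parameters.  Deterministic: running twice produces identical files.
#'
#' @param out_dir writable output directory.
#' @return the manifest, invisibly.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(name, files, params) {
    manifest[[name]] <<- list(files = basename(unlist(files)), params = params)
  }
  g <- fixture_spur_graph()
  add("spur_graph", write_graph_files(g, file.path(out_dir, "spur"), "spur"),
      list(spur_lengths_um = c(30, 49, 51), backbone_um = 300))
  for (gap in c(8, 12)) {
    g <- fixture_gap_graph(gap)
    add(sprintf("gap_%d", gap),
        write_graph_files(g, file.path(out_dir, sprintf("gap_%d", gap)), "gap"),
        list(gap_um = gap, segment_um = 100))
  }
  for (r in c(2, 3, 5)) {
    g <- fixture_axial_tube(r)
    add(sprintf("tube_r%d", r),
        write_graph_files(g, file.path(out_dir, sprintf("tube_r%d", r)), "tube"),
        list(radius_um = r, cube_um = 400, axis = "ML"))
  }
  g <- fixture_lattice_graph()
  add("lattice", write_graph_files(g, file.path(out_dir, "lattice"), "lattice"),
      list(n = 3, pitch_um = 100, edges_per_axis = 3 * 3 * 2))
  ph <- generate_cortex_phantom("half_cylinder",
                                layer_fractions = c(0.2, 0.3, 0.3, 0.2),
                                extent = c(320, 200, 160), spacing = 4)
  p <- file.path(out_dir, "half_cylinder.nrrd")
  write_nrrd(ph, p)
  add("half_cylinder", p,
      list(outer_radius_um = attr(ph, "outer_radius"),
           inner_radius_um = attr(ph, "inner_radius"),
           layer_fractions = c(0.2, 0.3, 0.3, 0.2)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
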