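#' Clip a vessel graph to a cubic control volume
#'
#' Segments crossing a face of the cube are cut at the face and the cut
#' points become \code{boundary} nodes; radii at cuts are linearly
#' interpolated.  Components with no boundary node are retained but
#' carry no flow.
#'
#' @param g a \code{vessel_graph} in um coordinates.
#' @param center um, centre of the control volume (length 3).
#' @param size um, cube edge length (default 400).
#' @return a clipped \code{vessel_graph} with attributes \code{center},
#'   \code{size} and \code{n_boundary_nodes}.
#' @export
clip_to_control_volume <- function(g, center, size = 400) {
  lo <- center - size / 2
  hi <- center + size / 2
  env <- new.env()
  env$nodes <- data.frame(id = integer(), x = numeric(), y = numeric(),
                          z = numeric(), kind = character())
  env$map <- new.env()   # original node id -> new id
  env$segments <- data.frame(id = integer(), node_a = integer(),
                             node_b = integer())
  env$polylines <- list(); env$radii <- list()
  new_node <- function(pos, kind, orig = NULL) {
    key <- if (!is.null(orig)) as.character(orig) else NULL
    if (!is.null(key) && !is.null(env$map[[key]])) return(env$map[[key]])
    id <- nrow(env$nodes) + 1L
    env$nodes[id, ] <- list(id, pos[1], pos[2], pos[3], kind)
    if (!is.null(key)) env$map[[key]] <- id
    id
  }
  add_seg <- function(p, r, ida, idb) {
    sid <- nrow(env$segments) + 1L
    env$segments[sid, ] <- list(sid, ida, idb)
    env$polylines[[sid]] <- p
    env$radii[[sid]] <- r
  }
  inside <- function(q) all(q >= lo - 1e-9) && all(q <= hi + 1e-9)
  for (s in seq_len(nrow(g$segments))) {
    p <- g$polylines[[s]]; r <- g$radii[[s]]
    pieces <- .clip_polyline_box(p, r, lo, hi)
    for (pc in pieces) {
      n <- nrow(pc$p)
      if (n < 2 || polyline_length(pc$p) <= 1e-9) next
      ida <- if (pc$cut_a) new_node(pc$p[1, ], "boundary")
             else new_node(pc$p[1, ], "interior", orig = g$segments$node_a[s])
      idb <- if (pc$cut_b) new_node(pc$p[n, ], "boundary")
             else new_node(pc$p[n, ], "interior", orig = g$segments$node_b[s])
      add_seg(pc$p, pc$r, ida, idb)
    }
  }
  # nodes sitting exactly on a face are boundary nodes too
  if (nrow(env$nodes)) {
    pos <- as.matrix(env$nodes[, c("x", "y", "z")])
    on_face <- apply(abs(sweep(pos, 2, lo)) < 1e-6, 1, any) |
      apply(abs(sweep(pos, 2, hi)) < 1e-6, 1, any)
    env$nodes$kind[on_face] <- "boundary"
  }
  out <- vessel_graph(env$nodes, env$segments, env$polylines, env$radii)
  attr(out, "center") <- center
  attr(out, "size") <- size
  attr(out, "n_boundary_nodes") <- sum(out$nodes$kind == "boundary")
  out
}

# Split a polyline at the box [lo, hi]; returns list of pieces, each
# list(p, r, cut_a, cut_b) where cut_* marks ends created by the cut.
.clip_polyline_box <- function(p, r, lo, hi) {
  n <- nrow(p)
  if (length(r) < n) r <- rep(r, length.out = n)
  eps <- 1e-9
  inside <- function(q) all(q >= lo - eps) && all(q <= hi + eps)
  pieces <- list()
  cur_p <- NULL; cur_r <- NULL; cur_cut_a <- FALSE
  flush <- function(cut_b) {
    if (!is.null(cur_p) && nrow(cur_p) >= 2)
      pieces[[length(pieces) + 1]] <<- list(p = cur_p, r = cur_r,
                                            cut_a = cur_cut_a, cut_b = cut_b)
    cur_p <<- NULL; cur_r <<- NULL; cur_cut_a <<- FALSE
  }
  for (i in seq_len(n - 1)) {
    a <- p[i, ]; b <- p[i + 1, ]
    ia <- inside(a); ib <- inside(b)
    # parametric entry/exit of [lo,hi] along a + t (b - a)
    t0 <- 0; t1 <- 1
    for (ax in 1:3) {
      dv <- b[ax] - a[ax]
      if (abs(dv) < eps) {
        if (a[ax] < lo[ax] - eps || a[ax] > hi[ax] + eps) { t0 <- 2; break }
      } else {
        ta <- (lo[ax] - a[ax]) / dv
        tb <- (hi[ax] - a[ax]) / dv
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
      }
    }
    if (t0 > t1 || t0 > 1) {  # wholly outside
      if (!is.null(cur_p)) flush(TRUE)
      next
    }
    pa <- a + t0 * (b - a); pb <- a + t1 * (b - a)
    ra <- r[i] + t0 * (r[i + 1] - r[i]); rb <- r[i] + t1 * (r[i + 1] - r[i])
    if (is.null(cur_p)) {
      cur_p <- matrix(pa, ncol = 3); cur_r <- ra
      cur_cut_a <- t0 > eps || !ia
    }
    cur_p <- rbind(cur_p, pb); cur_r <- c(cur_r, rb)
    if (t1 < 1 - eps) flush(TRUE)   # exits the box inside this interval
  }
  flush(FALSE)
  pieces
}

# Hydraulic conductance of one segment (viscosity = 1).
# "integrated": series resistance sum(8 dl / (pi r^4)) over polyline
# intervals (physically correct for varying radii); "mean_radius":
# pi rbar^4 / (8 L).
segment_conductance <- function(p, r, mode = c("integrated", "mean_radius")) {
  mode <- match.arg(mode)
  n <- nrow(p)
  if (length(r) < n) r <- rep(r, length.out = n)
  dl <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  L <- sum(dl)
  if (L <= 1e-9) return(Inf)
  if (mode == "mean_radius") {
    rbar <- sum(dl * (r[-1] + r[-n]) / 2) / L
    return(pi * rbar^4 / (8 * L))
  }
  rmid <- (r[-1] + r[-n]) / 2
  R <- sum(8 * dl / (pi * rmid^4))
  1 / R
}

#' Solve Hagen-Poiseuille network flow in a control volume
#'
#' Boundary nodes are held at the pressure profile of a unit gradient
#' (\code{P = -gradient . x}, so flow runs along \code{+gradient});
#' interior nodes satisfy conservation of flux.  Viscosity is unity.
#' Components without boundary nodes carry zero flow.
#'
#' @param gclip a clipped \code{vessel_graph}
#'   (\code{\link{clip_to_control_volume}}).
#' @param gradient unit pressure-gradient direction (length 3).
#' @param conductance_mode \code{"integrated"} (per-point series
#'   resistance, default) or \code{"mean_radius"}.
#' @return list: \code{node_pressures} (named by node id),
#'   \code{segment_fluxes} (signed, positive from \code{node_a} to
#'   \code{node_b}), \code{gradient}, \code{residual} (max interior
#'   conservation violation).
#' @export
solve_network_flow <- function(gclip, gradient,
                               conductance_mode = c("integrated", "mean_radius")) {
  conductance_mode <- match.arg(conductance_mode)
  gradient <- as.numeric(gradient)
  gradient <- gradient / sqrt(sum(gradient^2))
  nseg <- nrow(gclip$segments)
  nn <- nrow(gclip$nodes)
  flux <- numeric(nseg)
  pressures <- setNames(rep(NA_real_, nn), gclip$nodes$id)
  if (nn == 0 || nseg == 0)
    return(list(node_pressures = pressures, segment_fluxes = flux,
                gradient = gradient, residual = 0))
  is_bnd <- gclip$nodes$kind == "boundary"
  pos <- as.matrix(gclip$nodes[, c("x", "y", "z")])
  pbnd <- -as.numeric(pos %*% gradient)
  pressures[is_bnd] <- pbnd[is_bnd]
  cond <- vapply(seq_len(nseg), function(s)
    segment_conductance(gclip$polylines[[s]], gclip$radii[[s]],
                        conductance_mode), 0)
  cond[!is.finite(cond)] <- 0   # zero-length slivers carry no resistance path
  # flow-connected components: only those touching a boundary node flow
  comp <- graph_components(gclip)
  flowing <- unique(comp[is_bnd])
  idx <- setNames(seq_len(nn), as.character(gclip$nodes$id))
  active_int <- which(!is_bnd & comp %in% flowing)
  if (length(active_int)) {
    ai <- setNames(seq_along(active_int), gclip$nodes$id[active_int])
    trip <- list(); rhs <- numeric(length(active_int))
    diag_acc <- numeric(length(active_int))
    for (s in seq_len(nseg)) {
      if (cond[s] <= 0) next
      a <- idx[[as.character(gclip$segments$node_a[s])]]
      b <- idx[[as.character(gclip$segments$node_b[s])]]
      if (a == b) next
      for (side in 1:2) {
        u <- if (side == 1) a else b
        v <- if (side == 1) b else a
        ku <- ai[as.character(gclip$nodes$id[u])]
        if (is.na(ku)) next
        diag_acc[ku] <- diag_acc[ku] + cond[s]
        if (is_bnd[v]) rhs[ku] <- rhs[ku] + cond[s] * pbnd[v]
        else {
          kv <- ai[as.character(gclip$nodes$id[v])]
          if (!is.na(kv))
            trip[[length(trip) + 1]] <- c(ku, kv, -cond[s])
        }
      }
    }
    m <- if (length(trip)) do.call(rbind, trip) else matrix(numeric(0), ncol = 3)
    A <- Matrix::sparseMatrix(i = c(seq_along(diag_acc), m[, 1]),
                              j = c(seq_along(diag_acc), m[, 2]),
                              x = c(diag_acc, m[, 3]),
                              dims = rep(length(active_int), 2))
    sol <- tryCatch(as.numeric(Matrix::solve(A, rhs)), error = function(e) NULL)
    if (is.null(sol)) {
      warning("singular interior cluster dropped from the flow solve")
      sol <- rep(NA_real_, length(active_int))
    }
    pressures[active_int] <- sol
  }
  # fluxes: Q = g * (P_a - P_b), positive a -> b
  for (s in seq_len(nseg)) {
    a <- idx[[as.character(gclip$segments$node_a[s])]]
    b <- idx[[as.character(gclip$segments$node_b[s])]]
    pa <- pressures[a]; pb <- pressures[b]
    flux[s] <- if (is.na(pa) || is.na(pb) || cond[s] <= 0) 0
               else cond[s] * (pa - pb)
  }
  # conservation residual at interior nodes
  resid <- 0
  if (length(active_int)) {
    net <- numeric(nn)
    for (s in seq_len(nseg)) {
      a <- idx[[as.character(gclip$segments$node_a[s])]]
      b <- idx[[as.character(gclip$segments$node_b[s])]]
      net[a] <- net[a] - flux[s]
      net[b] <- net[b] + flux[s]
    }
    resid <- max(abs(net[active_int]))
  }
  list(node_pressures = pressures, segment_fluxes = flux,
       gradient = gradient, residual = resid)
}

# Signed flux through the plane axis = coord, positive in +axis
# direction, summed over all polyline crossings.
.plane_flux <- function(gclip, flux, axis, coord) {
  tot <- 0
  for (s in seq_len(nrow(gclip$segments))) {
    if (flux[s] == 0) next
    x <- gclip$polylines[[s]][, axis]
    below <- x < coord
    cr <- which(below[-length(below)] != below[-1])
    for (i in cr) {
      sgn <- if (x[i + 1] > x[i]) 1 else -1
      tot <- tot + sgn * flux[s]
    }
  }
  tot
}

#' Compute the local flow tensor of a control volume
#'
#' Probes the clipped network with the three Cartesian unit pressure
#' gradients and measures the signed flux through the three centre cut
#' planes; the three flux vectors form the columns of the tensor
#' \code{k} (flux per unit pressure-drop gradient, viscosity 1).
#'
#' @param g a \code{vessel_graph} (unclipped).
#' @param center um, control-volume centre.
#' @param size um, cube edge (default 400).
#' @param conductance_mode see \code{\link{solve_network_flow}}.
#' @param symmetrize return \code{(k + t(k)) / 2} (default FALSE).
#' @return object of class \code{flow_tensor}: \code{k} (3 x 3),
#'   \code{conductance} (2000-point spherical mean),
#'   \code{n_boundary_nodes}, \code{center}, \code{size},
#'   \code{residual}.
#' @export
compute_flow_tensor <- function(g, center, size = 400,
                                conductance_mode = c("integrated", "mean_radius"),
                                symmetrize = FALSE) {
  conductance_mode <- match.arg(conductance_mode)
  gc <- clip_to_control_volume(g, center, size)
  k <- matrix(0, 3, 3)
  resid <- 0
  if (nrow(gc$segments)) {
    for (j in 1:3) {
      grad <- c(0, 0, 0); grad[j] <- 1
      sol <- solve_network_flow(gc, grad, conductance_mode)
      resid <- max(resid, sol$residual)
      for (i in 1:3)
        k[i, j] <- .plane_flux(gc, sol$segment_fluxes, i, center[i])
    }
  }
  if (symmetrize) k <- (k + t(k)) / 2
  structure(list(k = k, center = center, size = size,
                 conductance = spherical_conductance(k),
                 n_boundary_nodes = attr(gc, "n_boundary_nodes"),
                 residual = resid),
            class = "flow_tensor")
}

#' @exportS3Method base::print
print.flow_tensor <- function(x, ...) {
  cat("<flow_tensor> k (flux per unit pressure-drop gradient, mu = 1):\n")
  print(signif(x$k, 4))
  cat(sprintf("  spherical-mean conductance: %.4g; boundary nodes: %d\n",
              x$conductance, x$n_boundary_nodes))
  invisible(x)
}

#' Project a flow tensor onto cortical axes
#'
#' \code{k_pj = |k . n_pj|} (Euclidean norm of the tensor applied to the
#' penetrating, AP and ML unit vectors).
#'
#' @param k 3 x 3 tensor or a \code{flow_tensor}.
#' @param n_P,n_AP,n_ML axis vectors (normalised with a warning when
#'   not unit norm).
#' @return list: \code{k_P}, \code{k_AP}, \code{k_ML},
#'   \code{dominant} ("P", "AP", "ML" or NA on ties).
#' @export
project_tensor <- function(k, n_P, n_AP, n_ML) {
  if (inherits(k, "flow_tensor")) k <- k$k
  fix <- function(v) {
    v <- as.numeric(v)
    nv <- sqrt(sum(v^2))
    if (abs(nv - 1) > 1e-8) {
      warning("axis vector not unit norm; normalizing")
      v <- v / nv
    }
    v
  }
  proj <- c(P = sqrt(sum((k %*% fix(n_P))^2)),
            AP = sqrt(sum((k %*% fix(n_AP))^2)),
            ML = sqrt(sum((k %*% fix(n_ML))^2)))
  mx <- max(proj)
  top <- names(proj)[proj >= mx * (1 - 1e-12)]
  list(k_P = unname(proj["P"]), k_AP = unname(proj["AP"]),
       k_ML = unname(proj["ML"]),
       dominant = if (length(top) == 1) top else NA_character_)
}

#' Deterministic Fibonacci-sphere directions
#'
#' Golden-angle spiral of \code{n} quasi-uniform points on the unit
#' sphere.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n = 2000) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  phi <- i * ga
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Spherical-mean scalar conductance of a flow tensor
#'
#' Mean of \code{|k . n|} (Euclidean norm) over \code{n_points}
#' Fibonacci-sphere directions; deterministic for fixed
#' \code{n_points}.
#'
#' @param k 3 x 3 tensor or a \code{flow_tensor}.
#' @param n_points number of integration directions (default 2000).
#' @return scalar conductance >= 0.
#' @export
spherical_conductance <- function(k, n_points = 2000) {
  if (inherits(k, "flow_tensor")) k <- k$k
  dirs <- fibonacci_sphere(n_points)
  mean(sqrt(rowSums((dirs %*% t(k))^2)))
}

#' Flow tensors on a grid of control-volume centres
#'
#' @param g a \code{vessel_graph}.
#' @param centers n x 3 matrix of centre coordinates (um).
#' @param size um, cube edge (default 400).
#' @param ... passed to \code{\link{compute_flow_tensor}}.
#' @return data.frame with the centre, the 9 tensor entries and the
#'   spherical-mean conductance per control volume.
#' @export
flow_tensor_grid <- function(g, centers, size = 400, ...) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  rows <- lapply(seq_len(nrow(centers)), function(i) {
    ft <- compute_flow_tensor(g, centers[i, ], size, ...)
    data.frame(cx = centers[i, 1], cy = centers[i, 2], cz = centers[i, 3],
               kxx = ft$k[1, 1], kyx = ft$k[2, 1], kzx = ft$k[3, 1],
               kxy = ft$k[1, 2], kyy = ft$k[2, 2], kzy = ft$k[3, 2],
               kxz = ft$k[1, 3], kyz = ft$k[2, 3], kzz = ft$k[3, 3],
               conductance = ft$conductance,
               n_boundary_nodes = ft$n_boundary_nodes)
  })
  do.call(rbind, rows)
}
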