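#' Solve the cortical depth Laplace equation
#'
#' Finite-difference Laplace solution over cortex voxels with Dirichlet
#' conditions potential = 1 at the layer-1 outer surface (layer-1 voxels
#' 6-adjacent to non-cortex) and potential = 0 at the layer-6b inner
#' surface (layer-6b voxels 6-adjacent to non-cortex), and zero flux on
#' every other cortex boundary.  Solved by successive over-relaxation.
#'
#' @param annotation labelled integer \code{voxel_volume}; cortex labels
#'   taken from its \code{layers} attribute unless given explicitly.
#' @param layer1_label,layer6b_label labels of the outer and inner
#'   layers.
#' @param cortex_labels all labels counting as cortex.
#' @param tol convergence tolerance on the max update (default 1e-6).
#' @param omega SOR relaxation factor.
#' @param maxit iteration cap.
#' @return object of class \code{potential_field}: \code{potential}
#'   (\code{voxel_volume}, NA outside cortex), \code{state} (integer
#'   array: 0 outside, 1 free, 2 Dirichlet), \code{surface1} (logical
#'   array of the potential-1 surface), \code{iterations},
#'   \code{converged}, \code{annotation}.
#' @export
solve_laplace <- function(annotation, layer1_label = NULL,
                          layer6b_label = NULL, cortex_labels = NULL,
                          tol = 1e-6, omega = 1.9, maxit = 30000) {
  stopifnot(inherits(annotation, "voxel_volume"))
  layers <- attr(annotation, "layers")
  if (is.null(layer1_label)) {
    if (is.null(layers)) stop("no 'layers' attribute; give layer1_label")
    layer1_label <- layers$label[layers$name == "layer1"]
  }
  if (is.null(layer6b_label)) {
    if (is.null(layers)) stop("no 'layers' attribute; give layer6b_label")
    layer6b_label <- layers$label[layers$name == "layer6b"]
  }
  if (is.null(cortex_labels))
    cortex_labels <- if (!is.null(layers)) layers$label else
      sort(setdiff(unique(as.vector(annotation$data)), 0L))
  lab <- annotation$data
  d <- dim(lab)
  cortex <- array(lab %in% cortex_labels, d)
  out_adj <- .adjacent_to(!cortex, d)   # cortex voxels 6-adjacent to outside
  surf1 <- cortex & out_adj & array(lab == layer1_label, d)
  surf0 <- cortex & out_adj & array(lab == layer6b_label, d)
  if (!any(surf1))
    stop("no layer-1 surface found (layer-1 voxels adjacent to non-cortex)")
  if (!any(surf0))
    stop("no layer-6b surface found (layer-6b voxels adjacent to non-cortex)")
  state <- array(0L, d)
  state[cortex] <- 1L
  state[surf1 | surf0] <- 2L
  init <- array(0, d)
  init[cortex] <- 0.5
  init[surf1] <- 1
  init[surf0] <- 0
  sol <- .cpp_sor_laplace(as.numeric(init), as.integer(state), d,
                          omega, tol, as.integer(maxit))
  pot <- array(sol$potential, d)
  pot[!cortex] <- NA_real_
  structure(list(
    potential = voxel_volume(pot, annotation$spacing, annotation$axes,
                             annotation$origin),
    state = state, surface1 = surf1,
    iterations = sol$iterations,
    converged = sol$max_update <= tol,
    annotation = annotation), class = "potential_field")
}

# voxels with at least one TRUE 6-neighbour in `m`.  The volume faces
# count as non-adjacent (FALSE): an array face is a zero-flux cut
# through tissue, not a tissue surface.
.adjacent_to <- function(m, d) {
  out <- array(FALSE, d)
  pad <- function(shift_ax, dir) {
    r <- array(FALSE, d)
    n <- d[shift_ax]
    if (shift_ax == 1) {
      if (dir > 0) r[-n, , ] <- m[-1, , ] else r[-1, , ] <- m[-n, , ]
    } else if (shift_ax == 2) {
      if (dir > 0) r[, -n, ] <- m[, -1, ] else r[, -1, ] <- m[, -n, ]
    } else {
      if (dir > 0) r[, , -n] <- m[, , -1] else r[, , -1] <- m[, , -n]
    }
    r
  }
  for (ax in 1:3) for (dir in c(-1, 1)) out <- out | pad(ax, dir)
  out
}

#' @exportS3Method base::print
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field> %d cortex voxels, %d iterations%s\n",
              sum(x$state > 0), x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Build the isocortical flatmap projection
#'
#' Traces the ascending-gradient streamline from every cortex voxel to
#' the layer-1 surface; \code{flat_y} is the AP coordinate of the hit
#' point, \code{flat_x} the signed in-plane arc length along the
#' cortical surface contour from the dorsal-ridge reference (the
#' per-coronal-plane maximum-DV surface point, a straight cut in the AP
#' direction; negative on the lower-ML side).
#'
#' @param field a \code{potential_field}.
#' @param step streamline step in voxels (default 0.5).
#' @param lookup_spacings um, resolutions of the resampled lookup grids
#'   (default 10 and 20).
#' @return object of class \code{flatmap_projection}: \code{table}
#'   (data.frame voxel i/j/k, x/y/z um, flat_x, flat_y, depth,
#'   resolved), \code{n_unresolved}, \code{lookups} (per spacing: list
#'   of flat_x/flat_y/depth arrays), \code{spacing}.
#' @export
build_projection <- function(field, step = 0.5, lookup_spacings = c(10, 20)) {
  stopifnot(inherits(field, "potential_field"))
  ann <- field$annotation
  d <- dim(ann$data)
  sp <- ann$spacing
  state <- field$state
  # streamline targets: the potential-1 surface
  cstate <- array(0L, d)
  cstate[state > 0] <- 1L
  cstate[field$surface1] <- 2L
  starts <- which(state > 0)
  pot <- field$potential$data
  pot0 <- pot; pot0[is.na(pot0)] <- 0
  maxsteps <- as.integer(10 * max(d) / step)
  tr <- .cpp_trace_streamlines(as.numeric(pot0), as.integer(cstate), d,
                               as.integer(starts - 1L), step, maxsteps)
  hit_vox <- tr[, 1:3, drop = FALSE] + 1   # continuous 1-based voxel coords
  resolved <- tr[, 4] > 0
  hit_um <- sweep(sweep(hit_vox - 0.5, 2, sp, `*`), 2, ann$origin, `+`)
  # surface arc-length parameterisation per coronal (AP) slice
  arc <- .surface_arcs(field$surface1, d, sp, ann$origin)
  flat_x <- rep(NA_real_, length(starts))
  flat_y <- hit_um[, 3]
  kslice <- pmin(pmax(as.integer(round(hit_vox[, 3])), 1L), d[3])
  for (k in sort(unique(kslice[resolved]))) {
    a <- arc[[k]]
    if (is.null(a)) next
    sel <- which(resolved & kslice == k)
    if (!length(sel)) next
    # nearest surface voxel in-plane, plus tangential sub-voxel offset
    nn <- .nearest_rows(a$pos, hit_um[sel, 1:2, drop = FALSE])
    dxy <- hit_um[sel, 1:2, drop = FALSE] - a$smooth[nn, , drop = FALSE]
    flat_x[sel] <- a$arc[nn] + rowSums(dxy * a$tangent[nn, , drop = FALSE])
  }
  resolved <- resolved & !is.na(flat_x)
  ijk <- arrayInd(starts, d)
  tab <- data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                    x_um = (ijk[, 1] - 0.5) * sp[1] + ann$origin[1],
                    y_um = (ijk[, 2] - 0.5) * sp[2] + ann$origin[2],
                    z_um = (ijk[, 3] - 0.5) * sp[3] + ann$origin[3],
                    flat_x = flat_x, flat_y = flat_y,
                    depth = pot[starts], resolved = resolved)
  lookups <- lapply(lookup_spacings, function(s)
    .projection_lookup(tab, d, sp, ann$origin, s))
  names(lookups) <- as.character(lookup_spacings)
  structure(list(table = tab, n_unresolved = sum(!resolved),
                 lookups = lookups, spacing = sp,
                 annotation = ann), class = "flatmap_projection")
}

# Per-AP-slice surface contour parameterisation: ordered arc length from
# the dorsal ridge (max-DV surface voxel; ties -> median ML), signed by
# ML side.  Nearest-neighbour marching along the contour.
.surface_arcs <- function(surf1, d, sp, origin) {
  out <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    idx <- which(surf1[, , k], arr.ind = TRUE)
    if (!nrow(idx)) next
    pos <- cbind((idx[, 1] - 0.5) * sp[1] + origin[1],
                 (idx[, 2] - 0.5) * sp[2] + origin[2])
    n <- nrow(pos)
    arcv <- rep(NA_real_, n)
    maxdv <- max(pos[, 2])
    ties <- which(pos[, 2] > maxdv - 1e-9)
    ridge <- ties[order(abs(pos[ties, 1] - stats::median(pos[ties, 1])))][1]
    arcv[ridge] <- 0
    visited <- rep(FALSE, n); visited[ridge] <- TRUE
    step_max <- 3 * max(sp[1:2])
    march2 <- function(side_sign) {
      chain <- integer(0)
      cur <- ridge
      repeat {
        d2 <- (pos[, 1] - pos[cur, 1])^2 + (pos[, 2] - pos[cur, 2])^2
        d2[visited] <- Inf
        if (cur == ridge) {
          wrong <- sign(pos[, 1] - pos[ridge, 1]) != side_sign
          d2[wrong] <- Inf
        }
        nxt <- which.min(d2)
        if (!is.finite(d2[nxt]) || sqrt(d2[nxt]) > step_max) break
        chain <- c(chain, nxt)
        visited[nxt] <<- TRUE
        cur <- nxt
      }
      chain
    }
    order1 <- march2(1)
    order2 <- march2(-1)
    # one ordered pass through the whole contour, smoothed as a unit so
    # the moving average is unbiased at the ridge (the voxel staircase
    # would otherwise inflate arc lengths)
    full <- c(rev(order2), ridge, order1)
    sm <- .smooth_path(pos[full, , drop = FALSE], 5)
    dl <- sqrt(rowSums((sm[-1, , drop = FALSE] -
                          sm[-nrow(sm), , drop = FALSE])^2))
    cum <- c(0, cumsum(dl))
    cum <- cum - cum[which(full == ridge)]
    # re-zero at the interpolated apex (parabolic fit of DV vs arc around
    # the discrete maximum); degenerate (flat-top) contours keep the
    # ridge voxel as reference
    im <- which.max(sm[, 2])
    if (im > 1 && im < nrow(sm)) {
      y0 <- sm[im - 1, 2]; y1 <- sm[im, 2]; y2 <- sm[im + 1, 2]
      denom <- y0 - 2 * y1 + y2
      if (abs(denom) > 1e-9) {
        delta <- 0.5 * (y0 - y2) / denom   # in units of local arc step
        h_arc <- (cum[im + 1] - cum[im - 1]) / 2
        apex <- cum[im] + delta * h_arc
        if (abs(apex) <= 2 * max(sp[1:2])) cum <- cum - apex
      }
    }
    # unit tangents for sub-voxel correction of hit points
    tangents <- sm
    nfull <- nrow(sm)
    for (i in seq_len(nfull)) {
      a <- max(1, i - 1); b <- min(nfull, i + 1)
      tv <- sm[b, ] - sm[a, ]
      nv <- sqrt(sum(tv^2))
      tangents[i, ] <- if (nv > 0) tv / nv else c(0, 0)
    }
    arcv[full] <- cum
    out[[k]] <- list(pos = pos[full, , drop = FALSE], arc = cum,
                     smooth = sm, tangent = tangents)
  }
  out
}

# centred moving average of an ordered path (n x 2), window w (odd)
.smooth_path <- function(p, w = 5) {
  n <- nrow(p)
  if (n <= w) return(p)
  h <- w %/% 2
  out <- p
  for (i in seq_len(n)) {
    a <- max(1, i - h); b <- min(n, i + h)
    out[i, ] <- colMeans(p[a:b, , drop = FALSE])
  }
  out
}

.nearest_rows <- function(ref, query) {
  vapply(seq_len(nrow(query)), function(i) {
    which.min((ref[, 1] - query[i, 1])^2 + (ref[, 2] - query[i, 2])^2)
  }, 0L)
}

# Nearest-voxel lookup grids of flat_x / flat_y / depth at spacing s um.
.projection_lookup <- function(tab, d, sp, origin, s) {
  dims <- pmax(1L, as.integer(round(d * sp / s)))
  fx <- array(NA_real_, dims); fy <- fx; dp <- fx
  cx <- pmin(pmax(as.integer(ceiling((tab$x_um - origin[1]) / s)), 1L), dims[1])
  cy <- pmin(pmax(as.integer(ceiling((tab$y_um - origin[2]) / s)), 1L), dims[2])
  cz <- pmin(pmax(as.integer(ceiling((tab$z_um - origin[3]) / s)), 1L), dims[3])
  lin <- cx + dims[1] * (cy - 1) + dims[1] * dims[2] * (cz - 1)
  ok <- tab$resolved
  fx[lin[ok]] <- tab$flat_x[ok]
  fy[lin[ok]] <- tab$flat_y[ok]
  dp[lin[ok]] <- tab$depth[ok]
  list(flat_x = fx, flat_y = fy, depth = dp, spacing = s)
}

#' @exportS3Method base::print
print.flatmap_projection <- function(x, ...) {
  cat(sprintf("<flatmap_projection> %d cortex voxels, %d unresolved\n",
              nrow(x$table), x$n_unresolved))
  invisible(x)
}

#' Project a signal onto the cortical flatmap
#'
#' Aggregates a registered signal volume (or point set) per flat-map
#' pixel, restricted to selected layers, using the chosen reducer.
#' Flat pixels with no contributing voxels are missing (NA), not zero.
#'
#' @param signal a \code{voxel_volume} on the annotation grid, or a
#'   data.frame of points (\code{x_um, y_um, z_um}, optional
#'   \code{value}).
#' @param proj a \code{flatmap_projection}.
#' @param layers optional vector of annotation labels to include
#'   (default: all cortex).
#' @param reducer \code{"mean"}, \code{"max"} or \code{"sum"}.
#' @param flat_bin um, flat-pixel edge length (default 20).
#' @return list: \code{image} (matrix flat_x bins x flat_y bins, NA =
#'   missing), \code{x_breaks}, \code{y_breaks}.
#' @export
project_signal <- function(signal, proj, layers = NULL,
                           reducer = c("mean", "max", "sum"),
                           flat_bin = 20) {
  reducer <- match.arg(reducer)
  stopifnot(inherits(proj, "flatmap_projection"))
  tab <- proj$table[proj$table$resolved, , drop = FALSE]
  ann <- proj$annotation
  if (!is.null(layers)) {
    d <- dim(ann$data)
    lin <- tab$i + d[1] * (tab$j - 1) + d[1] * d[2] * (tab$k - 1)
    tab <- tab[ann$data[lin] %in% layers, , drop = FALSE]
  }
  if (inherits(signal, "voxel_volume")) {
    if (!identical(dim(signal$data), dim(ann$data)))
      stop("signal volume must be on the annotation grid")
    d <- dim(signal$data)
    lin <- tab$i + d[1] * (tab$j - 1) + d[1] * d[2] * (tab$k - 1)
    vals <- as.numeric(signal$data[lin])
    fx <- tab$flat_x; fy <- tab$flat_y
  } else {
    pts <- signal
    ijk <- point_to_voxel(ann, as.matrix(pts[, c("x_um", "y_um", "z_um")]))
    key <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
    tkey <- paste(tab$i, tab$j, tab$k)
    m <- match(key, tkey)
    ok <- !is.na(m)
    vals <- if ("value" %in% names(pts)) pts$value[ok] else rep(1, sum(ok))
    fx <- tab$flat_x[m[ok]]; fy <- tab$flat_y[m[ok]]
  }
  if (!length(fx))
    return(list(image = matrix(NA_real_, 0, 0), x_breaks = numeric(0),
                y_breaks = numeric(0)))
  xb <- seq(floor(min(fx) / flat_bin) * flat_bin,
            ceiling(max(fx) / flat_bin) * flat_bin + flat_bin, by = flat_bin)
  yb <- seq(floor(min(fy) / flat_bin) * flat_bin,
            ceiling(max(fy) / flat_bin) * flat_bin + flat_bin, by = flat_bin)
  ix <- findInterval(fx, xb, rightmost.closed = TRUE)
  iy <- findInterval(fy, yb, rightmost.closed = TRUE)
  img <- matrix(NA_real_, length(xb) - 1, length(yb) - 1)
  f <- switch(reducer, mean = mean, max = max, sum = sum)
  agg <- tapply(vals, list(ix, iy), f)
  img[cbind(as.integer(rownames(agg))[row(agg)],
            as.integer(colnames(agg))[col(agg)])] <- as.numeric(agg)
  list(image = img, x_breaks = xb, y_breaks = yb)
}
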