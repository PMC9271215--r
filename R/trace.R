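#' Skeletonize a binary vessel mask
#'
#' Topology-preserving 3D curve thinning honouring the 26-neighbor rule
#' for foreground: simple points are peeled in order of increasing
#' distance-transform value until only the one-voxel-wide centreline
#' remains; connected components and cycles of the mask are preserved.
#'
#' @param mask logical \code{voxel_volume} with isotropic spacing.
#' @return an object of class \code{skeleton}: \code{voxels} (n x 3
#'   1-based indices), \code{spacing}, \code{dim}, \code{origin},
#'   \code{radius_um} (filled by \code{\link{measure_radii}}).
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "voxel_volume"))
  sp <- mask$spacing
  if (max(sp) - min(sp) > 1e-9)
    stop("mask spacing is anisotropic (", paste(signif(sp, 4), collapse = "x"),
         "); interpolate to isotropic spacing first (interpolate_isotropic)")
  d <- dim(mask$data)
  skel <- .cpp_skeletonize(as.logical(mask$data), d)
  vox <- which(array(skel, d))
  structure(list(
    voxels = arrayInd(vox, d),
    radius_um = NULL,
    spacing = sp, dim = d, origin = mask$origin), class = "skeleton")
}

#' @exportS3Method base::print
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d voxels at %.3g um spacing%s\n", nrow(x$voxels),
              x$spacing[1],
              if (is.null(x$radius_um)) "" else " (radii measured)"))
  invisible(x)
}

#' Measure per-skeleton-voxel radii from the binary mask
#'
#' The radius at a centreline voxel is its Euclidean distance to the
#' nearest background voxel, in micrometres.
#'
#' @param mask logical \code{voxel_volume} the skeleton came from.
#' @param skel a \code{skeleton}.
#' @return the skeleton with \code{radius_um} filled.
#' @export
measure_radii <- function(mask, skel) {
  stopifnot(inherits(mask, "voxel_volume"), inherits(skel, "skeleton"))
  d <- dim(mask$data)
  lin <- skel$voxels[, 1] + d[1] * (skel$voxels[, 2] - 1) +
    d[1] * d[2] * (skel$voxels[, 3] - 1)
  if (any(!mask$data[lin]))
    stop("skeleton voxel outside the mask")
  edt <- .cpp_edt(as.logical(mask$data), d, mask$spacing)
  skel$radius_um <- edt[lin]
  skel
}

#' Build a vessel graph from a skeleton
#'
#' Skeleton voxels with a number of 26-neighbors different from 2 become
#' nodes; degree-2 chains are collapsed into polyline segments.  Short
#' internode segments (length below \code{max(2 * mean_radius,
#' min_internode_um)}) between branch nodes are contracted: the two
#' nodes merge at the segment midpoint and incident segments are
#' re-anchored there, which also fuses the multi-voxel junction clusters
#' thinning can leave.
#'
#' @param skel a \code{skeleton} with measured radii.
#' @param min_internode_um um, floor of the contraction threshold.
#' @return a \code{vessel_graph} in micrometre coordinates.
#' @export
build_graph <- function(skel, min_internode_um = 10) {
  stopifnot(inherits(skel, "skeleton"))
  n <- nrow(skel$voxels)
  if (n == 0) return(vessel_graph())
  if (is.null(skel$radius_um))
    skel$radius_um <- rep(skel$spacing[1], n)
  d <- skel$dim
  vox <- skel$voxels
  lin <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
  pos <- sweep(sweep(vox - 0.5, 2, skel$spacing, `*`), 2, skel$origin, `+`)
  # 26-neighbour adjacency via linear-index lookup
  lut <- integer(prod(d))
  lut[lin] <- seq_len(n)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    if (o[3] < 0 || (o[3] == 0 && (o[2] < 0 || (o[2] == 0 && o[1] < 0))))
      next  # count each unordered pair once
    nb <- vox[, 1] + o[1] + d[1] * (vox[, 2] + o[2] - 1) +
      d[1] * d[2] * (vox[, 3] + o[3] - 1)
    ok <- vox[, 1] + o[1] >= 1 & vox[, 1] + o[1] <= d[1] &
      vox[, 2] + o[2] >= 1 & vox[, 2] + o[2] <= d[2] &
      vox[, 3] + o[3] >= 1 & vox[, 3] + o[3] <= d[3]
    nbi <- ifelse(ok, lut[pmax(nb, 1)], 0L)
    hit <- which(ok & nbi > 0)
    if (length(hit))
      edges <- rbind(edges, cbind(hit, nbi[hit]))
  }
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  deg <- integer(n)
  t1 <- tabulate(edges[, 1], n); t2 <- tabulate(edges[, 2], n)
  deg <- t1 + t2
  g <- .chains_to_graph_vox(pos, skel$radius_um, edges, deg)
  # voxel chains zig-zag between diagonal and straight steps, which
  # inflates Euclidean polyline length by up to ~10%; endpoint-anchored
  # smoothing recovers the underlying centreline length
  g$polylines <- lapply(g$polylines, .smooth_polyline3, w = 5)
  g <- refresh_graph(g)
  g <- contract_short_internodes(g, min_internode_um)
  g
}

# centred moving average of interior polyline points; endpoints fixed
.smooth_polyline3 <- function(p, w = 5) {
  n <- nrow(p)
  if (n <= 3) return(p)
  h <- w %/% 2
  out <- p
  for (i in 2:(n - 1)) {
    a <- max(1, i - h); b <- min(n, i + h)
    out[i, ] <- colMeans(p[a:b, , drop = FALSE])
  }
  out
}

# chain walk over the voxel graph (like .chains_to_graph but with loop
# handling for node-free cycles)
.chains_to_graph_vox <- function(pts, radii, edges, deg) {
  n <- nrow(pts)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  is_node <- deg != 2
  node_pts <- which(is_node)
  visited_chain <- rep(FALSE, n)
  nodes <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), kind = character())
  pt2node <- integer(n)
  add_node <- function(p) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, pts[p, 1], pts[p, 2], pts[p, 3], "interior")
    pt2node[p] <<- id
    id
  }
  for (p in node_pts) add_node(p)
  segments <- data.frame(id = integer(), node_a = integer(), node_b = integer())
  polylines <- list(); rads <- list()
  used <- vector("list", n)  # per point: used adjacency slot flags
  for (p in seq_len(n)) used[[p]] <- rep(FALSE, length(adj[[p]]))
  sid <- 0L
  emit <- function(path) {
    sid <<- sid + 1L
    segments[sid, ] <<- list(sid, pt2node[path[1]], pt2node[path[length(path)]])
    polylines[[sid]] <<- pts[path, , drop = FALSE]
    rads[[sid]] <<- radii[path]
  }
  for (start in node_pts) {
    for (ei in seq_along(adj[[start]])) {
      if (used[[start]][ei]) next
      used[[start]][ei] <- TRUE
      path <- c(start)
      prev <- start
      cur <- adj[[start]][ei]
      # mark the back-slot of the first step
      back <- which(adj[[cur]] == prev & !used[[cur]])
      if (length(back)) used[[cur]][back[1]] <- TRUE
      repeat {
        path <- c(path, cur)
        if (is_node[cur]) break
        visited_chain[cur] <- TRUE
        nxt_slots <- which(!used[[cur]])
        if (!length(nxt_slots)) break
        ns <- nxt_slots[1]
        used[[cur]][ns] <- TRUE
        nxt <- adj[[cur]][ns]
        back <- which(adj[[nxt]] == cur & !used[[nxt]])
        if (length(back)) used[[nxt]][back[1]] <- TRUE
        prev <- cur; cur <- nxt
      }
      emit(path)
    }
  }
  # node-free cycles: remaining unvisited degree-2 points
  repeat {
    rem <- which(!is_node & !visited_chain & !(seq_len(n) %in% which(pt2node > 0)))
    rem <- rem[vapply(rem, function(p) any(!used[[p]]), TRUE)]
    if (!length(rem)) break
    start <- rem[1]
    add_node(start)
    is_node[start] <- TRUE
    ei <- which(!used[[start]])[1]
    used[[start]][ei] <- TRUE
    path <- c(start)
    prev <- start
    cur <- adj[[start]][ei]
    back <- which(adj[[cur]] == prev & !used[[cur]])
    if (length(back)) used[[cur]][back[1]] <- TRUE
    repeat {
      path <- c(path, cur)
      if (cur == start) break
      visited_chain[cur] <- TRUE
      nxt_slots <- which(!used[[cur]])
      if (!length(nxt_slots)) break
      ns <- nxt_slots[1]
      used[[cur]][ns] <- TRUE
      nxt <- adj[[cur]][ns]
      back <- which(adj[[nxt]] == cur & !used[[nxt]])
      if (length(back)) used[[nxt]][back[1]] <- TRUE
      prev <- cur; cur <- nxt
    }
    emit(path)
  }
  vessel_graph(nodes, segments, polylines, rads)
}

#' Contract short internode segments
#'
#' Internode segments joining two branch nodes whose length is below
#' \code{max(2 * mean_radius, min_um)} are removed shortest-first; their
#' nodes merge at the segment midpoint and incident segments re-anchor
#' to the merged node.
#'
#' @param g a \code{vessel_graph}.
#' @param min_um um, absolute length floor of the rule.
#' @return the contracted \code{vessel_graph}.
#' @export
contract_short_internodes <- function(g, min_um = 10) {
  repeat {
    deg <- node_degrees(g)
    len <- g$segments$length_um
    thr <- pmax(2 * g$segments$mean_radius_um, min_um)
    a <- as.character(g$segments$node_a); b <- as.character(g$segments$node_b)
    cand <- which(len < thr & deg[a] >= 3 & deg[b] >= 3 &
                    g$segments$node_a != g$segments$node_b)
    if (!length(cand)) break
    s <- cand[which.min(len[cand])]
    na <- g$segments$node_a[s]; nb <- g$segments$node_b[s]
    pa <- unlist(g$nodes[g$nodes$id == na, c("x", "y", "z")])
    pb <- unlist(g$nodes[g$nodes$id == nb, c("x", "y", "z")])
    mid <- (pa + pb) / 2
    g$nodes[g$nodes$id == na, c("x", "y", "z")] <- as.list(mid)
    g$segments <- g$segments[-s, , drop = FALSE]
    g$polylines[[s]] <- NULL
    g$radii[[s]] <- NULL
    rownames(g$segments) <- NULL
    # rewire nb -> na and re-anchor touching polyline ends
    for (i in seq_len(nrow(g$segments))) {
      touched <- FALSE
      if (g$segments$node_a[i] == nb) { g$segments$node_a[i] <- na; touched <- TRUE }
      if (g$segments$node_b[i] == nb) { g$segments$node_b[i] <- na; touched <- TRUE }
      if (g$segments$node_a[i] == na) {
        g$polylines[[i]][1, ] <- mid; touched <- TRUE
      }
      if (g$segments$node_b[i] == na) {
        g$polylines[[i]][nrow(g$polylines[[i]]), ] <- mid; touched <- TRUE
      }
      if (touched) invisible(NULL)
    }
    g$nodes <- g$nodes[g$nodes$id != nb, , drop = FALSE]
    # degenerate self-loops created by the merge (parallel edges that
    # collapsed) are dropped when essentially zero length
    g <- refresh_graph(g)
    drop <- which(g$segments$node_a == g$segments$node_b &
                    g$segments$length_um < min_um)
    if (length(drop)) {
      g$segments <- g$segments[-drop, , drop = FALSE]
      g$polylines[drop] <- NULL
      g$radii[drop] <- NULL
      rownames(g$segments) <- NULL
      g <- refresh_graph(g)
    }
  }
  refresh_graph(g)
}

#' Reconnect loose endpoints
#'
#' Endpoint pairs with mutual distance at most \code{max_gap} um are
#' joined by straight segments: greedy nearest pair first, each endpoint
#' participating in at most one reconnection, the two ends of one
#' segment never joined to each other.  Ties break on lowest node id.
#'
#' @param g a \code{vessel_graph}.
#' @param max_gap um, maximum gap to close (default 10).
#' @param collapse collapse the resulting degree-2 joints into single
#'   segments (default TRUE).
#' @return the reconnected \code{vessel_graph}.
#' @export
reconnect_endpoints <- function(g, max_gap = 10, collapse = TRUE) {
  deg <- node_degrees(g)
  eps <- g$nodes$id[deg[as.character(g$nodes$id)] == 1 &
                      g$nodes$kind != "boundary"]
  if (length(eps) < 2) return(g)
  P <- as.matrix(g$nodes[match(eps, g$nodes$id), c("x", "y", "z")])
  # segment owning each endpoint (degree-1: unique)
  own <- vapply(eps, function(id)
    which(g$segments$node_a == id | g$segments$node_b == id)[1], 0L)
  pairs <- NULL
  for (i in seq_along(eps)) for (j in seq_along(eps)) {
    if (j <= i) next
    dd <- sqrt(sum((P[i, ] - P[j, ])^2))
    if (dd <= max_gap && own[i] != own[j])
      pairs <- rbind(pairs, c(i, j, dd))
  }
  if (is.null(pairs)) return(g)
  pairs <- pairs[order(pairs[, 3], eps[pairs[, 1]], eps[pairs[, 2]]), ,
                 drop = FALSE]
  usedp <- rep(FALSE, length(eps))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (usedp[i] || usedp[j]) next
    usedp[i] <- usedp[j] <- TRUE
    sid <- if (nrow(g$segments)) max(g$segments$id) + 1L else 1L
    ri <- .endpoint_radius(g, eps[i]); rj <- .endpoint_radius(g, eps[j])
    g$segments <- rbind(g$segments, data.frame(
      id = sid, node_a = eps[i], node_b = eps[j],
      length_um = pairs[k, 3], mean_radius_um = mean(c(ri, rj))))
    g$polylines[[length(g$polylines) + 1]] <- rbind(P[i, ], P[j, ])
    g$radii[[length(g$radii) + 1]] <- c(ri, rj)
  }
  rownames(g$segments) <- NULL
  g <- refresh_graph(g)
  if (collapse) g <- collapse_interior_nodes(g)
  g
}

.endpoint_radius <- function(g, node_id) {
  s <- which(g$segments$node_a == node_id | g$segments$node_b == node_id)[1]
  if (is.na(s)) return(NA_real_)
  r <- g$radii[[s]]
  if (g$segments$node_a[s] == node_id) r[1] else r[length(r)]
}

#' Prune spur (fur) artifacts
#'
#' Terminal segments (at least one node of degree 1) shorter than
#' \code{min_len} um are removed, shortest first, with degree-2 joints
#' collapsed between removals, iterating to a fixed point.  Cycles and
#' through-segments are never removed.  Isolated segments (both ends
#' free) count as their own furs unless \code{keep_isolated}.
#'
#' @param g a \code{vessel_graph}.
#' @param min_len um, length threshold (default 50).
#' @param keep_isolated keep isolated short segments (default FALSE).
#' @return the pruned \code{vessel_graph}.
#' @export
prune_spurs <- function(g, min_len = 50, keep_isolated = FALSE) {
  repeat {
    deg <- node_degrees(g)
    a <- as.character(g$segments$node_a); b <- as.character(g$segments$node_b)
    free_a <- deg[a] == 1; free_b <- deg[b] == 1
    terminal <- (free_a | free_b) & g$segments$node_a != g$segments$node_b
    isolated <- free_a & free_b
    cand <- terminal & g$segments$length_um < min_len
    if (keep_isolated) cand <- cand & !isolated
    idx <- which(cand)
    if (!length(idx)) break
    s <- idx[which.min(g$segments$length_um[idx])]
    g$segments <- g$segments[-s, , drop = FALSE]
    g$polylines[[s]] <- NULL
    g$radii[[s]] <- NULL
    rownames(g$segments) <- NULL
    g <- refresh_graph(drop_orphan_nodes(g))
    g <- collapse_interior_nodes(g)
  }
  refresh_graph(drop_orphan_nodes(g))
}

#' Connectivity quality-control filter
#'
#' Total vessel length per graph node within an ROI; ROIs below
#' \code{min_ratio} um/node are flagged for exclusion.
#'
#' @param g a \code{vessel_graph}.
#' @param roi_mask optional logical \code{voxel_volume}; when given,
#'   length and nodes are restricted to the mask.
#' @param min_ratio um/node threshold (default 250).
#' @return list: \code{pass}, \code{ratio} (um/node; NA when the ROI has
#'   no nodes), \code{length_um}, \code{n_nodes}.
#' @export
qc_connectivity_filter <- function(g, roi_mask = NULL, min_ratio = 250) {
  if (is.null(roi_mask)) {
    len <- graph_total_length(g)
    nn <- nrow(g$nodes)
  } else {
    stopifnot(inherits(roi_mask, "voxel_volume"))
    len <- 0
    for (i in seq_len(nrow(g$segments))) {
      rs <- .resample_polyline(g$polylines[[i]], g$radii[[i]],
                               min(roi_mask$spacing) / 2)
      if (!nrow(rs$mid)) next
      ijk <- point_to_voxel(roi_mask, rs$mid)
      inside <- .in_mask(roi_mask, ijk)
      len <- len + sum(rs$dl[inside])
    }
    ijk <- point_to_voxel(roi_mask, as.matrix(g$nodes[, c("x", "y", "z")]))
    nn <- sum(.in_mask(roi_mask, ijk))
  }
  if (nn == 0) return(list(pass = FALSE, ratio = NA_real_,
                           length_um = len, n_nodes = 0L))
  ratio <- len / nn
  list(pass = ratio >= min_ratio, ratio = ratio, length_um = len,
       n_nodes = as.integer(nn))
}

.in_mask <- function(vol, ijk) {
  d <- dim(vol$data)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  val <- rep(FALSE, nrow(ijk))
  if (any(ok)) {
    lin <- ijk[ok, 1] + d[1] * (ijk[ok, 2] - 1) + d[1] * d[2] * (ijk[ok, 3] - 1)
    val[ok] <- as.logical(vol$data[lin])
  }
  val
}

#' Full mask-to-graph tracing pipeline
#'
#' Skeletonization, radius measurement, graph building, endpoint
#' reconnection (10 um) and spur pruning (50 um), in the standard
#' order.
#'
#' @param mask logical isotropic \code{voxel_volume}.
#' @param reconnect_gap um (default 10).
#' @param min_spur um (default 50).
#' @param min_internode um (default 10).
#' @return a cleaned \code{vessel_graph}.
#' @export
trace_vessels <- function(mask, reconnect_gap = 10, min_spur = 50,
                          min_internode = 10) {
  skel <- skeletonize(mask)
  skel <- measure_radii(mask, skel)
  g <- build_graph(skel, min_internode_um = min_internode)
  g <- reconnect_endpoints(g, max_gap = reconnect_gap)
  prune_spurs(g, min_len = min_spur)
}
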