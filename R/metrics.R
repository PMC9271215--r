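# Arc-length resampling of a polyline: splits every polyline interval
# into pieces no longer than `step` and returns piece midpoints, piece
# lengths and linearly interpolated radii at the midpoints.
.resample_polyline <- function(p, r, step) {
  if (is.null(p) || nrow(p) < 2)
    return(list(mid = matrix(numeric(0), ncol = 3), dl = numeric(0),
                rad = numeric(0)))
  mids <- list(); dls <- list(); rads <- list()
  for (i in seq_len(nrow(p) - 1)) {
    a <- p[i, ]; b <- p[i + 1, ]
    L <- sqrt(sum((b - a)^2))
    if (L == 0) next
    ra <- r[min(i, length(r))]; rb <- r[min(i + 1, length(r))]
    k <- max(1L, as.integer(ceiling(L / step)))
    t0 <- (seq_len(k) - 1) / k
    t1 <- seq_len(k) / k
    tm <- (t0 + t1) / 2
    mids[[length(mids) + 1]] <- cbind(a[1] + tm * (b[1] - a[1]),
                                      a[2] + tm * (b[2] - a[2]),
                                      a[3] + tm * (b[3] - a[3]))
    dls[[length(dls) + 1]] <- rep(L / k, k)
    rads[[length(rads) + 1]] <- ra + tm * (rb - ra)
  }
  if (!length(mids))
    return(list(mid = matrix(numeric(0), ncol = 3), dl = numeric(0),
                rad = numeric(0)))
  list(mid = do.call(rbind, mids), dl = unlist(dls), rad = unlist(rads))
}

#' Per-region vascular statistics
#'
#' Apportions vessel length to atlas regions by arc length of the
#' polylines within each region's voxels (boundary-clipped, not
#' whole-segment), assigns branch nodes to the region containing them,
#' and reports volumes, length density, branching density,
#' length-weighted mean radius and the large-vessel length fraction.
#'
#' @param graph a \code{vessel_graph} in um coordinates.
#' @param annotation labelled integer \code{voxel_volume} in the same
#'   frame.
#' @param large_radius_um radius threshold for the large-vessel length
#'   fraction (5 um for display-scale vessels; 3 um for the "large
#'   vasculature" analyses).
#' @param step um, arc-length resampling step (default half the finest
#'   annotation spacing).
#' @param include_background include label 0 in the output (default
#'   FALSE).
#' @return data.frame with one row per region: \code{region_id},
#'   \code{volume_mm3}, \code{total_length_um},
#'   \code{length_density_m_mm3}, \code{n_branch_nodes},
#'   \code{branch_density_mm3}, \code{mean_radius_um} (length-weighted),
#'   \code{mean_radius_unweighted_um}, \code{large_vessel_fraction}.
#' @export
region_vascular_stats <- function(graph, annotation, large_radius_um = 5,
                                  step = NULL,
                                  include_background = FALSE) {
  stopifnot(inherits(graph, "vessel_graph"), inherits(annotation, "voxel_volume"))
  ext <- vol_extent(annotation) + annotation$origin
  if (nrow(graph$nodes)) {
    bb <- rbind(apply(graph$nodes[, c("x", "y", "z")], 2, range))
    if (any(bb[1, ] < annotation$origin - 1e-6) || any(bb[2, ] > ext + 1e-6))
      stop("graph coordinates fall outside the annotation frame; ",
           "check that the two are in the same coordinate system")
  }
  if (is.null(step)) step <- min(annotation$spacing) / 2
  labs <- sort(unique(as.vector(annotation$data)))
  if (!include_background) labs <- setdiff(labs, 0L)
  vox_mm3 <- prod(annotation$spacing) / 1e9
  counts <- tabulate(match(as.vector(annotation$data), labs), length(labs))
  res <- data.frame(region_id = labs,
                    volume_mm3 = counts * vox_mm3,
                    total_length_um = 0, n_branch_nodes = 0L,
                    mean_radius_um = NA_real_,
                    mean_radius_unweighted_um = NA_real_,
                    large_vessel_fraction = NA_real_)
  acc_len <- setNames(numeric(length(labs)), labs)
  acc_rl <- acc_len   # sum radius * dl
  acc_large <- acc_len
  seg_regions <- vector("list", nrow(graph$segments))
  for (i in seq_len(nrow(graph$segments))) {
    rs <- .resample_polyline(graph$polylines[[i]], graph$radii[[i]], step)
    if (!nrow(rs$mid)) next
    lab_i <- .label_at(annotation, rs$mid)
    keep <- lab_i %in% labs
    if (!any(keep)) next
    li <- as.character(lab_i[keep])
    tl <- tapply(rs$dl[keep], li, sum)
    acc_len[names(tl)] <- acc_len[names(tl)] + tl
    trl <- tapply(rs$dl[keep] * rs$rad[keep], li, sum)
    acc_rl[names(trl)] <- acc_rl[names(trl)] + trl
    tlg <- tapply(rs$dl[keep] * (rs$rad[keep] > large_radius_um), li, sum)
    acc_large[names(tlg)] <- acc_large[names(tlg)] + tlg
    seg_regions[[i]] <- unique(lab_i[keep])
  }
  bn <- graph$nodes[graph$nodes$kind == "branch", , drop = FALSE]
  if (nrow(bn)) {
    lab_b <- .label_at(annotation, as.matrix(bn[, c("x", "y", "z")]))
    tb <- table(as.character(lab_b[lab_b %in% labs]))
    res$n_branch_nodes <- as.integer(tb[as.character(res$region_id)])
    res$n_branch_nodes[is.na(res$n_branch_nodes)] <- 0L
  }
  res$total_length_um <- as.numeric(acc_len[as.character(res$region_id)])
  # segment-unweighted mean radius per region (whole segments touching it)
  for (k in seq_along(labs)) {
    touch <- vapply(seg_regions, function(s) labs[k] %in% s, TRUE)
    if (any(touch))
      res$mean_radius_unweighted_um[k] <-
        mean(graph$segments$mean_radius_um[touch])
  }
  rl <- as.numeric(acc_rl[as.character(res$region_id)])
  res$mean_radius_um <- ifelse(res$total_length_um > 0,
                               rl / res$total_length_um, NA_real_)
  lg <- as.numeric(acc_large[as.character(res$region_id)])
  res$large_vessel_fraction <- ifelse(res$total_length_um > 0,
                                      lg / res$total_length_um, NA_real_)
  res$length_density_m_mm3 <- ifelse(res$volume_mm3 > 0,
    (res$total_length_um / res$volume_mm3) / 1e6, NA_real_)
  res$length_density_um_um3 <- res$length_density_m_mm3 * 1e-3
  res$branch_density_mm3 <- ifelse(res$volume_mm3 > 0,
    res$n_branch_nodes / res$volume_mm3, NA_real_)
  res[, c("region_id", "volume_mm3", "total_length_um",
          "length_density_m_mm3", "length_density_um_um3",
          "n_branch_nodes", "branch_density_mm3", "mean_radius_um",
          "mean_radius_unweighted_um", "large_vessel_fraction")]
}

.label_at <- function(annotation, xyz) {
  ijk <- point_to_voxel(annotation, xyz)
  d <- dim(annotation$data)
  ijk[, 1] <- pmin(pmax(ijk[, 1], 1L), d[1])
  ijk[, 2] <- pmin(pmax(ijk[, 2], 1L), d[2])
  ijk[, 3] <- pmin(pmax(ijk[, 3], 1L), d[3])
  lin <- ijk[, 1] + d[1] * (ijk[, 2] - 1) + d[1] * d[2] * (ijk[, 3] - 1)
  annotation$data[lin]
}

#' Voxelized vessel density volume
#'
#' Sums vessel length (or branch-node count, or radius-weighted length)
#' into cubic bins and smooths with a Gaussian filter of
#' \code{smooth_sigma_bins} bins, the standard 20 um / sigma = 2
#' rendering grid.
#'
#' @param graph a \code{vessel_graph}.
#' @param bin um, bin edge length (default 20); must be > 0.
#' @param smooth_sigma_bins Gaussian sigma in bins (default 2; 0
#'   disables smoothing).
#' @param extent um, volume extent (default: graph bounding box padded
#'   by one bin).
#' @param mode \code{"length"} (um per bin), \code{"branch"} (nodes per
#'   bin) or \code{"radius_length"} (um * um per bin).
#' @return a \code{voxel_volume} on the bin grid.
#' @export
voxelize_density <- function(graph, bin = 20, smooth_sigma_bins = 2,
                             extent = NULL,
                             mode = c("length", "branch", "radius_length")) {
  mode <- match.arg(mode)
  if (bin <= 0) stop("bin size must be positive")
  if (is.null(extent)) {
    if (!nrow(graph$nodes)) extent <- rep(bin, 3)
    else {
      pmax_ <- apply(do.call(rbind, graph$polylines), 2, max)
      extent <- (floor(pmax_ / bin) + 1) * bin
    }
  }
  dims <- pmax(1L, as.integer(ceiling(extent / bin)))
  acc <- array(0, dims)
  if (mode == "branch") {
    bn <- graph$nodes[graph$nodes$kind == "branch", , drop = FALSE]
    if (nrow(bn)) {
      ijk <- pmin(pmax(floor(as.matrix(bn[, c("x", "y", "z")]) / bin) + 1, 1),
                  matrix(dims, nrow(bn), 3, byrow = TRUE))
      for (r in seq_len(nrow(ijk)))
        acc[ijk[r, 1], ijk[r, 2], ijk[r, 3]] <-
          acc[ijk[r, 1], ijk[r, 2], ijk[r, 3]] + 1
    }
  } else {
    for (i in seq_len(nrow(graph$segments))) {
      rs <- .resample_polyline(graph$polylines[[i]], graph$radii[[i]], bin / 4)
      if (!nrow(rs$mid)) next
      ijk <- floor(rs$mid / bin) + 1
      ijk[, 1] <- pmin(pmax(ijk[, 1], 1), dims[1])
      ijk[, 2] <- pmin(pmax(ijk[, 2], 1), dims[2])
      ijk[, 3] <- pmin(pmax(ijk[, 3], 1), dims[3])
      w <- if (mode == "length") rs$dl else rs$dl * rs$rad
      lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1) + dims[1] * dims[2] * (ijk[, 3] - 1)
      tw <- tapply(w, lin, sum)
      acc[as.integer(names(tw))] <- acc[as.integer(names(tw))] + as.numeric(tw)
    }
  }
  if (smooth_sigma_bins > 0) acc <- gaussian_smooth3(acc, smooth_sigma_bins)
  voxel_volume(acc, rep(bin, 3))
}

#' Per-layer vascular profile
#'
#' Splits regional statistics by cortical layer using the annotation's
#' layer labels.
#'
#' @param graph a \code{vessel_graph}.
#' @param annotation labelled \code{voxel_volume} whose labels encode
#'   layers, with a \code{layers} attribute (data.frame label/name) or
#'   an explicit \code{layers} argument.
#' @param layers optional data.frame with columns \code{label} and
#'   \code{name} mapping annotation labels to layer names.
#' @param ... passed to \code{\link{region_vascular_stats}}.
#' @return the regional statistics table with a \code{layer} column.
#' @export
layer_profile <- function(graph, annotation, layers = NULL, ...) {
  if (is.null(layers)) layers <- attr(annotation, "layers")
  if (is.null(layers))
    stop("annotation lacks layer labels: provide a 'layers' mapping")
  st <- region_vascular_stats(graph, annotation, ...)
  st$layer <- layers$name[match(st$region_id, layers$label)]
  st[!is.na(st$layer), , drop = FALSE]
}
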