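#' Resample a volume to isotropic spacing with cubic interpolation
#'
#' Each axis whose spacing differs from \code{target_spacing} is
#' resampled with a Catmull-Rom cubic kernel (exact on affine
#' intensity profiles); borders are linearly extrapolated so affine
#' exactness holds up to the volume edge.  The physical extent is
#' preserved to within one voxel.
#'
#' @param vol a \code{voxel_volume}.
#' @param target_spacing um, the isotropic output spacing (default 1).
#' @return a \code{voxel_volume} at the target spacing.  When the target
#'   is coarser than the input on every axis the result carries
#'   attribute \code{downsampled = TRUE}.
#' @export
interpolate_isotropic <- function(vol, target_spacing = 1) {
  stopifnot(inherits(vol, "voxel_volume"), target_spacing > 0)
  a <- vol$data
  storage.mode(a) <- "double"
  ext <- vol_extent(vol)
  for (ax in 1:3) {
    if (abs(vol$spacing[ax] - target_spacing) < 1e-12) next
    nold <- dim(a)[ax]
    nnew <- max(2L, as.integer(round(ext[ax] / target_spacing)))
    W <- .cubic_resample_matrix(nold, vol$spacing[ax], nnew, target_spacing)
    a <- .apply_axis_matrix(a, W, ax)
  }
  out <- voxel_volume(a, rep(target_spacing, 3), vol$axes, vol$origin)
  if (all(target_spacing > vol$spacing + 1e-12))
    attr(out, "downsampled") <- TRUE
  out
}

# Sparse nnew x nold Catmull-Rom resampling matrix mapping samples at
# centres (j-0.5)*hold to centres (i-0.5)*hnew.  Out-of-range support
# points are linearly extrapolated, which keeps the operator exact on
# affine profiles.
.cubic_resample_matrix <- function(nold, hold, nnew, hnew) {
  tnew <- ((seq_len(nnew) - 0.5) * hnew) / hold + 0.5   # in old sample units
  j0 <- floor(tnew)
  u <- tnew - j0
  # Catmull-Rom weights for samples j0-1 .. j0+2
  w <- cbind(
    (-u^3 + 2 * u^2 - u) / 2,
    (3 * u^3 - 5 * u^2 + 2) / 2,
    (-3 * u^3 + 4 * u^2 + u) / 2,
    (u^3 - u^2) / 2)
  ii <- rep(seq_len(nnew), 4)
  jj <- as.integer(c(j0 - 1, j0, j0 + 1, j0 + 2))
  ww <- as.numeric(w)
  # fold out-of-range columns back with linear extrapolation:
  # f[0] = 2 f[1] - f[2];  f[n+1] = 2 f[n] - f[n-1]  (recursively)
  tri <- data.frame(i = ii, j = jj, w = ww)
  res <- list()
  push <- function(i, j, w) res[[length(res) + 1]] <<- c(i, j, w)
  for (k in seq_len(nrow(tri))) {
    i <- tri$i[k]; j <- tri$j[k]; w <- tri$w[k]
    if (w == 0) next
    while (j < 1 || j > nold) {
      if (j < 1) { push(i, 1, 2 * w); w <- -w; j <- 2 - j + 0 }
      else { push(i, nold, 2 * w); w <- -w; j <- 2 * nold - j }
      # after reflection: f[1-d] ~ 2 f[1] - f[1+d]
    }
    push(i, j, w)
  }
  m <- do.call(rbind, res)
  Matrix::sparseMatrix(i = m[, 1], j = m[, 2], x = m[, 3],
                       dims = c(nnew, nold))
}

# multiply a resampling matrix along one axis of a 3D array
.apply_axis_matrix <- function(a, W, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[ax])
  out <- as.matrix(W %*% m)
  dnew <- d; dnew[ax] <- nrow(W)
  outp <- array(out, dim = dnew[perm])
  aperm(outp, order(perm))
}

#' Subtract the autofluorescent background channel
#'
#' Per-voxel \code{signal - background}, clamped at zero (negative
#' fluorescence is non-physical).
#'
#' @param signal,background \code{voxel_volume}s of identical shape and
#'   spacing.
#' @return a \code{voxel_volume}.
#' @export
subtract_background <- function(signal, background) {
  stopifnot(inherits(signal, "voxel_volume"),
            inherits(background, "voxel_volume"))
  if (!identical(dim(signal$data), dim(background$data)))
    stop(sprintf("shape mismatch: signal %s vs background %s",
                 paste(dim(signal$data), collapse = "x"),
                 paste(dim(background$data), collapse = "x")))
  if (max(abs(signal$spacing - background$spacing)) > 1e-9)
    stop("spacing mismatch between channels")
  voxel_volume(pmax(signal$data - background$data, 0), signal$spacing,
               signal$axes, signal$origin)
}

#' Non-empty-space foreground statistics
#'
#' The "non-empty space average" is the mean intensity over voxels
#' exceeding a small absolute floor (a fraction of the volume's 99.9th
#' percentile), i.e. a tissue mask that excludes empty imaging space.
#'
#' @param vol a \code{voxel_volume} (typically background-subtracted).
#' @param floor_frac fraction of the 99.9th percentile used as floor.
#' @return list with \code{nonempty_mean} and \code{nonempty_mask}.
#' @export
foreground_stats <- function(vol, floor_frac = 0.01) {
  v <- vol$data
  hi <- stats::quantile(v, 0.999, names = FALSE)
  floor_abs <- floor_frac * hi
  mask <- v > floor_abs
  if (!any(mask))
    stop("volume has no non-empty voxels (all at or below the floor)")
  m <- mean(v[mask])
  if (m <= 0) stop("non-empty space average is zero; invalid input")
  list(nonempty_mean = m, nonempty_mask = mask)
}

#' Binarize vasculature
#'
#' A voxel is foreground when it passes either rule: (a) a fixed
#' threshold of \code{fixed_k} times the non-empty space average, or
#' (b) a threshold of \code{adaptive_k} times that average after
#' subtracting a circular 35\% local ranking (percentile) filter,
#' evaluated per in-plane (ML-DV) slice.
#'
#' @param vol a \code{voxel_volume}, background-subtracted.
#' @param stats optional precomputed \code{\link{foreground_stats}}.
#' @param rank_radius_um circular footprint radius of the ranking
#'   filter, um (applied in the ML-DV plane).
#' @param rank_percentile percentile of the ranking filter, in (0, 1).
#' @param fixed_k multiplier for rule (a).
#' @param adaptive_k multiplier for rule (b).
#' @return logical \code{voxel_volume} mask with attribute
#'   \code{nonempty_mean}.
#' @export
binarize_vessels <- function(vol, stats = NULL, rank_radius_um = 20,
                             rank_percentile = 0.35, fixed_k = 6,
                             adaptive_k = 2.4) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (is.null(stats)) stats <- foreground_stats(vol)
  m <- stats$nonempty_mean
  if (!is.finite(m) || m <= 0) stop("invalid non-empty space average")
  if (abs(vol$spacing[1] - vol$spacing[2]) > 1e-9)
    stop("in-plane spacing must be isotropic for the circular rank filter")
  v <- vol$data
  mask_a <- v >= fixed_k * m
  radius_px <- rank_radius_um / vol$spacing[1]
  d <- dim(v)
  mask_b <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    rk <- .cpp_rank_filter2d(v[, , k], radius_px, rank_percentile)
    mask_b[, , k] <- (v[, , k] - rk) >= adaptive_k * m
  }
  out <- voxel_volume(mask_a | mask_b, vol$spacing, vol$axes, vol$origin)
  attr(out, "nonempty_mean") <- m
  out
}
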