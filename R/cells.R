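#' Published 2D-to-3D conversion factors
#'
#' Dimensionless multipliers converting single-plane (2D) cell counts to
#' 3D counts: 1.4 for cytoplasmic signals, 1.5 for nuclear signals, 2.1
#' for pericytes.
#'
#' @export
conversion_factors <- c(cytoplasmic = 1.4, nuclear = 1.5, pericyte = 2.1)

#' Detect cell candidates as radius-constrained local maxima
#'
#' Strict local maxima of the intensity image within a circular (2D) or
#' ellipsoidal (3D, spacing-aware) neighbourhood of \code{radius_um},
#' above an intensity floor.  Plateau ties resolve to the
#' lexicographically smallest coordinate.  Candidates are returned
#' sorted by position.
#'
#' @param img numeric matrix (2D plane) or \code{voxel_volume}.
#' @param radius_um exclusion radius in um (default 8).
#' @param spacing um per pixel for matrix input (scalar or length 2).
#' @param floor intensity floor; default the non-empty-space mean of the
#'   image (see \code{\link{foreground_stats}}).
#' @return data.frame: \code{x_um, y_um[, z_um], peak_intensity}.
#' @export
detect_candidates <- function(img, radius_um = 8, spacing = 1, floor = NULL) {
  if (inherits(img, "voxel_volume")) {
    a <- img$data
    sp <- img$spacing
    dims <- dim(a)
  } else {
    a <- img
    sp <- rep(spacing, length.out = 2)
    dims <- dim(a)
  }
  nd <- length(dims)
  if (is.null(floor)) {
    hi <- stats::quantile(a, 0.999, names = FALSE)
    m <- a > 0.01 * hi
    floor <- if (any(m)) mean(a[m]) else Inf
  }
  # neighbourhood offsets within radius_um (excluding the centre)
  rng <- lapply(seq_len(nd), function(ax) {
    r <- floor(radius_um / sp[ax])
    (-r):r
  })
  offs <- as.matrix(do.call(expand.grid, rng))
  keep <- rowSums(sweep(offs, 2, sp[seq_len(nd)], `*`)^2) <= radius_um^2 &
    rowSums(abs(offs)) > 0
  offs <- offs[keep, , drop = FALSE]
  # lexicographic priority: .shift_nd(a, o) holds the neighbour at p - o,
  # so the neighbour is column-major-prior when -o is negative, i.e. o > 0
  prior <- offs[, nd] > 0
  for (ax in rev(seq_len(nd - 1)))
    prior <- prior | (rowSums(abs(offs[, (ax + 1):nd, drop = FALSE])) == 0 &
                        offs[, ax] > 0)
  cand <- a > floor
  for (r in seq_len(nrow(offs))) {
    if (!any(cand)) break
    o <- offs[r, ]
    shifted <- .shift_nd(a, o, fill = -Inf)
    cand <- cand & !(shifted > a | (shifted == a & prior[r]))
  }
  idx <- which(cand)
  if (!length(idx)) {
    out <- data.frame(x_um = numeric(), y_um = numeric())
    if (nd == 3) out$z_um <- numeric()
    out$peak_intensity <- numeric()
    return(out)
  }
  ai <- arrayInd(idx, dims)
  out <- data.frame(x_um = (ai[, 1] - 0.5) * sp[1],
                    y_um = (ai[, 2] - 0.5) * sp[2])
  if (nd == 3) out$z_um <- (ai[, 3] - 0.5) * sp[3]
  out$peak_intensity <- a[idx]
  ord <- do.call(order, as.list(out[, seq_len(nd), drop = FALSE]))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shift an array by integer offset, filling exposed cells
.shift_nd <- function(a, o, fill = -Inf) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (ax in seq_along(d)) {
    s <- seq_len(d[ax]) - o[ax]
    ok <- s >= 1 & s <= d[ax]
    dst[[ax]] <- which(ok)
    src[[ax]] <- s[ok]
  }
  if (any(vapply(dst, length, 0L) == 0)) return(out)
  if (length(d) == 2) out[dst[[1]], dst[[2]]] <- a[src[[1]], src[[2]]]
  else out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# bilinear sample of a matrix at physical (um) coordinates; zero outside
.bilinear_sample <- function(img, xs, ys, spacing) {
  px <- xs / spacing[1] + 0.5
  py <- ys / spacing[2] + 0.5
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  get <- function(i, j) {
    v <- matrix(0, length(i), 1)
    ok <- i >= 1 & i <= nrow(img) & j >= 1 & j <= ncol(img)
    v[ok] <- img[cbind(i[ok], j[ok])]
    v
  }
  as.numeric(
    get(x0, y0) * (1 - fx) * (1 - fy) + get(x0 + 1, y0) * fx * (1 - fy) +
    get(x0, y0 + 1) * (1 - fx) * fy + get(x0 + 1, y0 + 1) * fx * fy)
}

#' Extract multi-resolution patches around a candidate
#'
#' Crops the small window (101 x 101 um at 101 x 101 px) and the large
#' window (501 x 501 um at 201 x 201 px, bilinear resampling), each with
#' a companion marker plane that is zero except for value 1 at the
#' candidate location; optionally a full-frame context image resampled
#' to 201 x 201 px.  Regions outside the image are zero-padded and the
#' padded fraction reported.
#'
#' @param img numeric matrix at \code{spacing} um/px.
#' @param candidate list or one-row data.frame with \code{x_um, y_um}.
#' @param spacing um per pixel (scalar or length 2).
#' @param include_full_frame also return the low-resolution full frame.
#' @param small_um,small_px,large_um,large_px,frame_px window geometry.
#' @return list: \code{small}, \code{small_marker}, \code{large},
#'   \code{large_marker}, optional \code{frame} and
#'   \code{frame_marker}, and \code{padded_fraction}.
#' @export
extract_patches <- function(img, candidate, spacing = 1,
                            include_full_frame = FALSE,
                            small_um = 101, small_px = 101L,
                            large_um = 501, large_px = 201L,
                            frame_px = 201L) {
  spacing <- rep(spacing, length.out = 2)
  x <- candidate$x_um[1]; y <- candidate$y_um[1]
  W <- nrow(img) * spacing[1]; H <- ncol(img) * spacing[2]
  if (x < 0 || y < 0 || x > W || y > H)
    stop("candidate lies outside the image")
  crop <- function(win_um, px) {
    cc <- seq(-(win_um / 2), win_um / 2, length.out = px)
    xs <- rep(x + cc, times = px)
    ys <- rep(y + cc, each = px)
    v <- .bilinear_sample(img, xs, ys, spacing)
    pad <- mean(xs < 0 | ys < 0 | xs > W | ys > H)
    list(m = matrix(v, px, px), pad = pad)
  }
  marker <- function(px) {
    m <- matrix(0, px, px)
    m[(px + 1) %/% 2, (px + 1) %/% 2] <- 1
    m
  }
  s <- crop(small_um, small_px)
  l <- crop(large_um, large_px)
  out <- list(small = s$m, small_marker = marker(small_px),
              large = l$m, large_marker = marker(large_px),
              padded_fraction = c(small = s$pad, large = l$pad))
  if (include_full_frame) {
    xs <- rep(seq(0, W, length.out = frame_px), times = frame_px)
    ys <- rep(seq(0, H, length.out = frame_px), each = frame_px)
    out$frame <- matrix(.bilinear_sample(img, xs, ys, spacing),
                        frame_px, frame_px)
    fm <- matrix(0, frame_px, frame_px)
    fi <- pmin(pmax(round(x / W * (frame_px - 1)) + 1, 1), frame_px)
    fj <- pmin(pmax(round(y / H * (frame_px - 1)) + 1, 1), frame_px)
    fm[fi, fj] <- 1
    out$frame_marker <- fm
  }
  out
}

#' Baseline handcrafted-feature cell classifier
#'
#' Thresholds on peak intensity, local contrast (centre intensity minus
#' patch median) and bright-blob size in the small window.  Stands in
#' for a learned model behind the same candidate/patch interface.
#'
#' @param min_contrast minimum centre-minus-median contrast.
#' @param blob_px acceptable range of above-half-peak blob pixel counts.
#' @param positive_class,negative_class labels to emit.
#' @return a classifier \code{function(patches, candidate)} returning a
#'   class label.
#' @export
baseline_blob_classifier <- function(min_contrast = 20,
                                     blob_px = c(3, 400),
                                     positive_class = "pericyte",
                                     negative_class = "other") {
  function(patches, candidate) {
    sm <- patches$small
    px <- dim(sm)[1]
    c0 <- (px + 1) %/% 2
    centre <- sm[c0, c0]
    contrast <- centre - stats::median(sm)
    win <- sm[max(1, c0 - 10):min(px, c0 + 10),
              max(1, c0 - 10):min(px, c0 + 10)]
    blob <- sum(win >= centre / 2)
    if (contrast >= min_contrast && blob >= blob_px[1] && blob <= blob_px[2])
      positive_class
    else negative_class
  }
}

#' Classify candidates with a pluggable classifier
#'
#' @param candidates data.frame from \code{\link{detect_candidates}}.
#' @param img image matrix the candidates came from.
#' @param classifier \code{function(patches, candidate) -> label}.
#' @param classes allowed class labels (two-bin pericyte mode by
#'   default; pass three labels for the nNOS mode).
#' @param spacing um per pixel.
#' @param ... passed to \code{\link{extract_patches}}.
#' @return the candidates with a \code{class} column.
#' @export
classify_candidates <- function(candidates, img,
                                classifier = baseline_blob_classifier(),
                                classes = c("pericyte", "other"),
                                spacing = 1, ...) {
  labels <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    patches <- extract_patches(img, candidates[i, , drop = FALSE],
                               spacing = spacing, ...)
    labels[i] <- classifier(patches, candidates[i, , drop = FALSE])
  }
  bad <- setdiff(unique(labels), classes)
  if (length(bad))
    stop("classifier returned labels outside the class set: ",
         paste(bad, collapse = ", "))
  candidates$class <- labels
  candidates
}

#' Estimate the 2D-to-3D conversion factor
#'
#' Pooled factor = 3D count / 2D count, rounded to one decimal; with
#' per-ROI count pairs, also the mean and SD of per-ROI ratios.
#'
#' @param count_2d total 2D count (> 0).
#' @param count_3d total 3D count.
#' @param roi_pairs optional data.frame/matrix with 2D and 3D counts per
#'   ROI (columns \code{count_2d}, \code{count_3d}).
#' @return object of class \code{conversion_factor}: \code{factor}
#'   (rounded pooled ratio), \code{pooled_ratio}, \code{per_roi_mean},
#'   \code{per_roi_sd}, \code{n_roi}.
#' @export
estimate_conversion_factor <- function(count_2d, count_3d, roi_pairs = NULL) {
  if (count_2d <= 0) stop("2D count must be positive")
  ratio <- count_3d / count_2d
  per_mean <- NA_real_; per_sd <- NA_real_; n_roi <- 0L
  if (!is.null(roi_pairs)) {
    roi_pairs <- as.data.frame(roi_pairs)
    rr <- roi_pairs$count_3d / roi_pairs$count_2d
    per_mean <- mean(rr); per_sd <- stats::sd(rr); n_roi <- length(rr)
    if (n_roi == 1) per_sd <- 0
  }
  structure(list(factor = round(ratio, 1), pooled_ratio = ratio,
                 per_roi_mean = per_mean, per_roi_sd = per_sd,
                 n_roi = n_roi), class = "conversion_factor")
}

#' @exportS3Method base::print
print.conversion_factor <- function(x, ...) {
  cat(sprintf("<conversion_factor> %.1f (pooled ratio %.3f", x$factor,
              x$pooled_ratio))
  if (x$n_roi > 0)
    cat(sprintf("; per-ROI %.2f +/- %.2f, n = %d", x$per_roi_mean,
                x$per_roi_sd, x$n_roi))
  cat(")\n")
  invisible(x)
}

#' Convert regional 2D counts to 3D densities
#'
#' density = (2D count x conversion factor) / region volume.
#'
#' @param counts data.frame with \code{region_id}, \code{count} and
#'   optionally \code{animal}.
#' @param factor a \code{conversion_factor}, or a bare number.
#' @param region_volumes named numeric vector, mm^3 per region id.
#' @return data.frame \code{region_id, density_mm3} (mean across
#'   animals when an \code{animal} column is present, with
#'   \code{n_animals}).
#' @export
compute_density <- function(counts, factor, region_volumes) {
  f <- if (inherits(factor, "conversion_factor")) factor$factor else factor
  counts <- as.data.frame(counts)
  miss <- setdiff(unique(as.character(counts$region_id)),
                  names(region_volumes))
  if (length(miss))
    stop("missing region volume for region(s): ", paste(miss, collapse = ", "))
  vols <- region_volumes[as.character(counts$region_id)]
  if (any(vols <= 0)) stop("region volumes must be positive")
  counts$density_mm3 <- counts$count * f / vols
  if (!"animal" %in% names(counts)) {
    return(counts[, c("region_id", "density_mm3")])
  }
  agg <- stats::aggregate(density_mm3 ~ region_id, counts, mean)
  nan <- stats::aggregate(density_mm3 ~ region_id, counts, length)
  agg$n_animals <- nan$density_mm3
  agg
}

#' Precision / recall / F1 of detections against ground truth
#'
#' One-to-one greedy nearest matching within \code{match_radius}.
#'
#' @param detections,truth data.frames with \code{x_um, y_um} and
#'   optionally \code{z_um}.
#' @param match_radius um (default 8).
#' @return list: \code{precision}, \code{recall}, \code{f1},
#'   \code{n_matched}.
#' @export
evaluate_detection <- function(detections, truth, match_radius = 8) {
  nd <- nrow(detections); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    prec <- if (nd == 0) NA_real_ else 0
    rec <- if (nt == 0) NA_real_ else 0
    return(list(precision = prec, recall = rec, f1 = 0, n_matched = 0L))
  }
  cols <- intersect(c("x_um", "y_um", "z_um"),
                    intersect(names(detections), names(truth)))
  D <- as.matrix(detections[, cols, drop = FALSE])
  T_ <- as.matrix(truth[, cols, drop = FALSE])
  pairs <- NULL
  for (i in seq_len(nd)) {
    d2 <- sqrt(colSums((t(T_) - D[i, ])^2))
    ok <- which(d2 <= match_radius)
    if (length(ok))
      pairs <- rbind(pairs, cbind(i, ok, d2[ok]))
  }
  nmatch <- 0L
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    du <- rep(FALSE, nd); tu <- rep(FALSE, nt)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!du[i] && !tu[j]) {
        du[i] <- tu[j] <- TRUE
        nmatch <- nmatch + 1L
      }
    }
  }
  prec <- nmatch / nd
  rec <- nmatch / nt
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f1 = f1, n_matched = nmatch)
}
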