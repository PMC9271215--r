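#' Voxel volume container
#'
#' A 3D scalar image together with its per-axis voxel spacing (in
#' micrometres), semantic axis labels and an origin offset.  The axis
#' convention throughout the package is axis 1 = ML (medial-lateral,
#' "x"), axis 2 = DV (dorsal-ventral, "y"), axis 3 = AP
#' (anterior-posterior, "z"); the centre of voxel \code{[i, j, k]}
#' (1-based) is at \code{origin + (c(i, j, k) - 0.5) * spacing} um.
#'
#' @param data 3D numeric, integer or logical array.
#' @param spacing numeric length-3, um per voxel along each axis; all > 0.
#' @param axes character length-3, a permutation of \code{c("ML","DV","AP")}.
#' @param origin numeric length-3, um offset of the volume corner.
#' @return An object of class \code{voxel_volume}.
#' @export
voxel_volume <- function(data, spacing, axes = c("ML", "DV", "AP"),
                         origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (um)")
  if (!setequal(axes, c("ML", "DV", "AP")))
    stop("'axes' must be a permutation of ML, DV, AP")
  structure(
    list(data = data, spacing = spacing, axes = axes,
         origin = as.numeric(origin)),
    class = "voxel_volume"
  )
}

#' @exportS3Method base::print
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels (%s)\n", d[1], d[2], d[3],
              paste(x$axes, collapse = "-")))
  cat(sprintf("  spacing: %s um; extent: %s um\n",
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(d * x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' Physical extent of a volume in micrometres
#' @param vol a \code{voxel_volume}.
#' @return numeric length-3 extent in um.
#' @export
vol_extent <- function(vol) dim(vol$data) * vol$spacing

#' Voxel-centre coordinates for given indices
#' @param vol a \code{voxel_volume}.
#' @param ijk integer matrix (n x 3) of 1-based voxel indices.
#' @return numeric matrix (n x 3) of um coordinates.
#' @export
voxel_centers <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk - 0.5, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' Voxel index containing a physical point
#' @param vol a \code{voxel_volume}.
#' @param xyz numeric matrix (n x 3) of um coordinates.
#' @return integer matrix (n x 3) of 1-based indices (unclamped).
#' @export
point_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  ijk <- sweep(xyz, 2, vol$origin, `-`)
  ijk <- sweep(ijk, 2, vol$spacing, `/`)
  matrix(as.integer(floor(ijk)) + 1L, ncol = 3)
}

# --- NRRD text I/O ---------------------------------------------------------
# Minimal NRRD support restricted to ascii/text encodings so that volumes
# remain plain text.  Covers the header fields the pipeline needs:
# dimension, sizes, spacings/space directions, type, encoding.

#' Write a volume as an ASCII-encoded NRRD file
#'
#' @param vol a \code{voxel_volume}.
#' @param path output file path (conventionally \code{.nrrd}).
#' @return \code{path}, invisibly.
#' @export
write_nrrd <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  is_int <- is.integer(vol$data) || is.logical(vol$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    "# vasculomap ascii volume",
    sprintf("type: %s", if (is_int) "int" else "double"),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %s", paste(format(vol$spacing, digits = 10), collapse = " ")),
    sprintf("axis mins: %s", paste(format(vol$origin, digits = 10), collapse = " ")),
    sprintf("labels: \"%s\" \"%s\" \"%s\"", vol$axes[1], vol$axes[2], vol$axes[3]),
    "encoding: ascii",
    ""
  ), con)
  vals <- if (is_int) as.integer(vol$data) else as.numeric(vol$data)
  writeLines(paste(format(vals, trim = TRUE, digits = 10, scientific = FALSE),
                   collapse = " "), con)
  invisible(path)
}

#' Read an ASCII-encoded NRRD file
#'
#' Only \code{encoding: ascii} / \code{text} NRRDs are supported (the
#' format the package writes).
#'
#' @param path NRRD file path.
#' @return a \code{voxel_volume}.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!grepl("^NRRD", lines[1]))
    stop("not a NRRD file: ", path)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("NRRD header not terminated by a blank line")
  hdr <- lines[2:(blank - 1)]
  hdr <- hdr[!grepl("^#", hdr)]
  fields <- list()
  for (h in hdr) {
    kv <- strsplit(h, ": ", fixed = TRUE)[[1]]
    fields[[tolower(kv[1])]] <- kv[2]
  }
  enc <- fields[["encoding"]]
  if (is.null(enc) || !enc %in% c("ascii", "text", "txt"))
    stop("only ascii-encoded NRRD supported, got encoding: ", enc)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  spacing <- if (!is.null(fields[["spacings"]]))
    as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(fields[["axis mins"]]))
    as.numeric(strsplit(fields[["axis mins"]], "\\s+")[[1]]) else c(0, 0, 0)
  axes <- c("ML", "DV", "AP")
  if (!is.null(fields[["labels"]])) {
    lb <- gsub("\"", "", strsplit(fields[["labels"]], "\\s+")[[1]])
    if (setequal(lb, axes)) axes <- lb
  }
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               quiet = TRUE)
  type <- fields[["type"]]
  if (!is.null(type) && grepl("int|short|char|long", type))
    vals <- as.integer(vals)
  voxel_volume(array(vals, dim = sizes), spacing = spacing, axes = axes,
               origin = origin)
}

# --- smoothing -------------------------------------------------------------

#' Separable Gaussian smoothing of a 3D array
#'
#' The kernel is truncated at 4 sigma and renormalised to unit sum, so
#' total mass is conserved exactly away from array borders.
#'
#' @param a 3D numeric array.
#' @param sigma standard deviation in voxels (scalar or length-3).
#' @return smoothed array of the same dimension.
#' @export
gaussian_smooth3 <- function(a, sigma) {
  sigma <- rep(as.numeric(sigma), length.out = 3)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(4 * s)))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    a <- .convolve_axis(a, k, ax)
  }
  a
}

# 1D convolution along axis `ax` with zero padding, via apply-free shifts
.convolve_axis <- function(a, k, ax) {
  d <- dim(a)
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, dim = d)
  for (o in -r:r) {
    w <- k[o + r + 1L]
    n <- d[ax]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    idx_dst <- which(ok)
    idx_src <- src[ok]
    if (ax == 1L) out[idx_dst, , ] <- out[idx_dst, , ] + w * a[idx_src, , ]
    else if (ax == 2L) out[, idx_dst, ] <- out[, idx_dst, ] + w * a[, idx_src, ]
    else out[, , idx_dst] <- out[, , idx_dst] + w * a[, , idx_src]
  }
  out
}
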