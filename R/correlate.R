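#' Average per-animal region tables into one region-mean table
#'
#' Each ROI is one data point: per-region mean of every numeric column
#' across animals.  Regions failing the vessel-connectivity QC are
#' excluded and listed in the \code{excluded_qc} attribute; regions
#' present in no table are dropped with a warning.
#'
#' @param tables list of data.frames sharing a \code{region_id} column.
#' @param qc optional data.frame \code{region_id, pass} from
#'   \code{\link{qc_connectivity_filter}} applied per region.
#' @return region-mean data.frame with \code{n_animals} per region.
#' @export
aggregate_by_region <- function(tables, qc = NULL) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  all <- do.call(rbind, lapply(seq_along(tables), function(i) {
    t <- as.data.frame(tables[[i]])
    t$.animal <- i
    t
  }))
  num_cols <- setdiff(names(all)[vapply(all, is.numeric, TRUE)],
                      c("region_id", ".animal"))
  out <- stats::aggregate(all[num_cols], by = list(region_id = all$region_id),
                          FUN = mean, na.rm = TRUE)
  cnt <- stats::aggregate(list(n_animals = all$.animal),
                          by = list(region_id = all$region_id),
                          FUN = function(x) length(unique(x)))
  out <- merge(out, cnt, by = "region_id")
  excluded <- character(0)
  if (!is.null(qc)) {
    fail <- qc$region_id[!qc$pass]
    excluded <- as.character(intersect(out$region_id, fail))
    out <- out[!out$region_id %in% fail, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "excluded_qc") <- excluded
  out
}

#' Pearson correlation with Bonferroni adjustment
#'
#' Pearson R over paired region means, two-sided p from the
#' t-distribution with n - 2 degrees of freedom, and
#' \code{p_adjusted = min(1, m * p)}.
#'
#' @param x,y numeric vectors paired over identical region sets, n >= 3.
#' @param m number of comparisons in the family (default 1).
#' @param pair_name optional label for the variable pair.
#' @return one-row data.frame: \code{pair, R, p_raw, p_adjusted, n_roi,
#'   m, sig_05, sig_005}.  Zero variance yields missing R and p.
#' @export
correlate_bonferroni <- function(x, y, m = 1, pair_name = "x~y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired ROIs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(pair = pair_name, R = NA_real_, p_raw = NA_real_,
                      p_adjusted = NA_real_, n_roi = n, m = m,
                      sig_05 = NA, sig_005 = NA))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  p <- ct$p.value
  padj <- min(1, m * p)
  data.frame(pair = pair_name, R = unname(ct$estimate), p_raw = p,
             p_adjusted = padj, n_roi = n, m = m,
             sig_05 = padj < 0.05, sig_005 = padj < 0.005)
}

#' All-pairs correlation matrix with Bonferroni correction
#'
#' Computes every pairwise Pearson correlation among the requested
#' columns, with the Bonferroni family size m equal to the number of
#' tested pairs (recorded in the output).
#'
#' @param data region-mean data.frame.
#' @param vars columns to correlate (default: all numeric except
#'   region_id / n_animals).
#' @return long-format data.frame, one row per variable pair.
#' @export
correlation_matrix <- function(data, vars = NULL) {
  if (is.null(vars))
    vars <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                    c("region_id", "n_animals"))
  pairs <- utils::combn(vars, 2)
  m <- ncol(pairs)
  do.call(rbind, lapply(seq_len(m), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    correlate_bonferroni(data[[a]], data[[b]], m = m,
                         pair_name = paste(a, b, sep = "~"))
  }))
}
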