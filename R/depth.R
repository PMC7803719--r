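#' Assign voxels to cortical depth quantile bins
#'
#' Computes bin edges at the empirical quantiles of the in-mask normalized
#' depths and assigns every in-mask voxel to one bin. Bin sizes differ by at
#' most one when depth values are distinct. A voxel lying exactly on an
#' interior edge goes to the lower-index (deeper) bin.
#'
#' @param depth_map Numeric vector of normalized depths in `[0, 1]`
#'   (0 = gray/white border, 1 = pial surface), one per voxel.
#' @param roi_mask Logical vector selecting the voxels to bin.
#' @param n_bins Number of depth bins. Default 5.
#' @return A `depth_binning`: list with `n_bins`, `edges`, `assignment`
#'   (bin index per voxel, `NA` outside the mask), `counts`, and `mean_depth`
#'   (mean normalized depth per bin).
#' @examples
#' depth_quantile_bins(seq(0.05, 0.95, by = 0.1), rep(TRUE, 10), n_bins = 5)
#' @export
depth_quantile_bins <- function(depth_map, roi_mask, n_bins = 5) {
  stopifnot(length(depth_map) == length(roi_mask), n_bins >= 1)
  roi_mask <- as.logical(roi_mask)
  d <- depth_map[roi_mask]
  if (length(d) == 0) stop("ROI mask selects no voxels", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1)) {
    stop("depth values must be finite and within [0, 1]", call. = FALSE)
  }
  if (length(d) < n_bins) {
    stop(sprintf("fewer in-mask voxels (%d) than depth bins (%d)",
                 length(d), n_bins), call. = FALSE)
  }
  edges <- unname(stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1),
                                  type = 7))
  if (any(diff(edges) <= 0)) {
    stop("degenerate depth quantiles: bin edges are not strictly increasing",
         call. = FALSE)
  }
  bin <- findInterval(d, edges, left.open = TRUE, rightmost.closed = TRUE)
  bin[d <= edges[1]] <- 1L
  assignment <- rep(NA_integer_, length(depth_map))
  assignment[roi_mask] <- bin
  structure(list(n_bins = n_bins,
                 edges = edges,
                 assignment = assignment,
                 counts = tabulate(bin, nbins = n_bins),
                 mean_depth = vapply(seq_len(n_bins),
                                     function(k) mean(d[bin == k]),
                                     numeric(1))),
            class = "depth_binning")
}

#' @export
print.depth_binning <- function(x, ...) {
  cat(sprintf("Depth binning: %d bins, %s voxels, mean depths %s\n",
              x$n_bins, paste(x$counts, collapse = "/"),
              paste(format(x$mean_depth, digits = 2), collapse = "/")))
  invisible(x)
}

#' Mean time course per depth bin
#'
#' Averages conditioned (percent-unit) voxel time series within each depth
#' bin of one ROI: an unweighted mean over voxels at every time sample.
#'
#' @param series Matrix (voxel x time sample) of conditioned series, indexed
#'   like `binning$assignment`.
#' @param binning A `depth_binning` for the ROI.
#' @param roi_mask Logical vector; voxels to include (must be covered by the
#'   binning).
#' @return A `depth_timecourses`: list with `mean` (bin x time matrix),
#'   `counts`, and `mean_depth` per bin.
#' @export
roi_depth_timecourse <- function(series, binning, roi_mask) {
  stopifnot(is.matrix(series), inherits(binning, "depth_binning"),
            nrow(series) == length(binning$assignment))
  roi_mask <- as.logical(roi_mask)
  assign <- binning$assignment
  assign[!roi_mask] <- NA_integer_
  out <- matrix(NA_real_, nrow = binning$n_bins, ncol = ncol(series))
  counts <- integer(binning$n_bins)
  for (k in seq_len(binning$n_bins)) {
    idx <- which(!is.na(assign) & assign == k)
    if (length(idx) == 0) {
      stop(sprintf("depth bin %d is empty after masking", k), call. = FALSE)
    }
    counts[k] <- length(idx)
    out[k, ] <- colMeans(series[idx, , drop = FALSE])
  }
  structure(list(mean = out, counts = counts, mean_depth = binning$mean_depth),
            class = "depth_timecourses")
}
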