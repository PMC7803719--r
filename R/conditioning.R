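#' Replace signal spikes with neighboring non-spike values
#'
#' Flags samples whose robust z-score exceeds `z_thresh` and replaces each
#' with the average of the closest non-spike time point on each side
#' (single-sided at the series edges). The robust score is the residual from
#' a running-median (k = 5) baseline divided by a noise scale estimated from
#' first differences (`mad(diff(x)) / sqrt(2)`), which is insensitive to both
#' spikes and slow drift; when that scale is zero (an otherwise constant
#' background) any nonzero residual counts as a spike.
#'
#' @param x Numeric time series (length >= 3).
#' @param z_thresh Robust z threshold. Default 5.
#' @return `x` with spikes replaced; attribute `n_spikes` gives the count.
#' @examples
#' despike(c(0, 0, 0, 50, 0, 0, 0))
#' @export
despike <- function(x, z_thresh = 5) {
  n <- length(x)
  if (n < 3) stop("despike needs at least 3 samples", call. = FALSE)
  stopifnot(all(is.finite(x)), z_thresh > 0)
  k <- min(5L, n - (n + 1L) %% 2L)  # odd, <= n
  base <- stats::runmed(x, k = k, endrule = "median")
  r <- x - base
  s <- stats::mad(diff(x)) / sqrt(2)
  spike <- if (s == 0) abs(r) > 0 else abs(r) / s > z_thresh
  if (all(spike)) {
    stop("all samples flagged as spikes; series cannot be despiked", call. = FALSE)
  }
  out <- x
  good <- which(!spike)
  for (i in which(spike)) {
    left <- good[good < i]
    right <- good[good > i]
    nb <- c(if (length(left)) x[max(left)], if (length(right)) x[min(right)])
    out[i] <- mean(nb)
  }
  attr(out, "n_spikes") <- sum(spike)
  out
}

#' Convert a time series to percent signal change
#'
#' Divides by the temporal mean, multiplies by 100, and subtracts 100, so the
#' output has mean exactly zero in percent-BOLD units.
#'
#' @param x Numeric time series with nonzero temporal mean.
#' @param label Optional label (voxel/bin id) used in the error message when
#'   the mean is zero.
#' @return Percent-signal-change series.
#' @examples
#' scale_percent(c(90, 110))
#' @export
scale_percent <- function(x, label = "series") {
  m <- mean(x)
  if (!is.finite(m) || abs(m) < 1e-12 * max(1, max(abs(x)))) {
    stop(sprintf("cannot scale %s to percent signal change: temporal mean is zero",
                 label), call. = FALSE)
  }
  100 * x / m - 100
}

#' Remove a polynomial trend by least squares
#'
#' Fits and removes a polynomial of degree `max_degree` (including the
#' constant), leaving a residual orthogonal to all polynomial basis terms.
#'
#' @param x Numeric time series, length > `max_degree + 1`.
#' @param max_degree Polynomial degree. Default 4.
#' @return Detrended series (zero mean).
#' @export
detrend_poly <- function(x, max_degree = 4) {
  n <- length(x)
  if (n <= max_degree + 1) {
    stop(sprintf("detrend_poly needs more than %d samples for degree %d (got %d)",
                 max_degree + 1, max_degree, n), call. = FALSE)
  }
  if (max_degree == 0) return(x - mean(x))
  tt <- seq_len(n)
  unname(stats::lm.fit(cbind(1, stats::poly(tt, max_degree)), x)$residuals)
}

#' Linearly resample a time series to a new sampling step
#'
#' Output samples lie at `0, dt_out, 2*dt_out, ...` up to and including the
#' last input time point (when it falls on the output grid); values are
#' linearly interpolated and grid points shared with the input are preserved
#' exactly.
#'
#' @param x Numeric time series.
#' @param dt_in Input sampling step in seconds.
#' @param dt_out Output sampling step in seconds.
#' @return Resampled series.
#' @examples
#' resample_linear(c(0, 2), 2.6, 1.3)  # 0, 1, 2
#' @export
resample_linear <- function(x, dt_in, dt_out) {
  stopifnot(dt_in > 0, dt_out > 0, length(x) >= 2)
  total <- (length(x) - 1) * dt_in
  if (dt_out > total) {
    stop(sprintf("output step %.3g s exceeds the series duration %.3g s",
                 dt_out, total), call. = FALSE)
  }
  t_in <- (seq_along(x) - 1) * dt_in
  t_out <- dt_out * (0:floor(total / dt_out + 1e-9))
  stats::approx(t_in, x, xout = pmin(t_out, total), method = "linear")$y
}

#' Condition one run of voxel time series
#'
#' Applies the fixed per-run conditioning chain to every voxel:
#' despike, scale to percent signal change, polynomial detrend, and linear
#' temporal resampling — in that order (the order is not configurable).
#'
#' @param mat Matrix (voxel x volume) of raw-unit series for one run.
#' @param tr Input sampling step (volume TR) in seconds.
#' @param dt_out Output sampling step in seconds. Default 1.3.
#' @param z_thresh Despiking threshold; `NULL` disables despiking. Default 5.
#' @param detrend_degree Polynomial degree for detrending; 0 removes only the
#'   mean. Default 4.
#' @return Matrix (voxel x resampled sample) in percent units; attribute
#'   `n_spikes` totals the spikes replaced across voxels.
#' @export
condition_run <- function(mat, tr, dt_out = 1.3, z_thresh = 5,
                          detrend_degree = 4) {
  stopifnot(is.matrix(mat))
  n_spikes <- 0L
  rows <- lapply(seq_len(nrow(mat)), function(v) {
    x <- mat[v, ]
    if (!is.null(z_thresh)) {
      x <- despike(x, z_thresh)
      n_spikes <<- n_spikes + attr(x, "n_spikes")
    }
    x <- scale_percent(x, label = sprintf("voxel %d", v))
    x <- detrend_poly(x, detrend_degree)
    resample_linear(x, tr, dt_out)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_spikes") <- n_spikes
  out
}
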