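#' Canonical double-gamma hemodynamic response function
#'
#' Samples a double-gamma HRF on a regular time grid. The kernel is the
#' difference of two gamma densities (response and undershoot lobes) and is
#' normalized to unit integral, so that convolving a sustained unit boxcar
#' yields a plateau of 1: per-depth response amplitudes are then expressed
#' directly in percent BOLD.
#'
#' @param dt Sampling step in seconds.
#' @param peak_delay Shape of the response gamma lobe (seconds; the lobe peaks
#'   near `peak_delay - 1` s with unit rate). Default 6.
#' @param undershoot_delay Shape of the undershoot gamma lobe (seconds).
#'   Default 16.
#' @param ratio Peak-to-undershoot amplitude ratio. Default 6.
#' @param duration Support of the sampled kernel in seconds; the kernel is
#'   truncated (and renormalized) beyond this point. Default 32.
#' @return Numeric vector of kernel weights at times `0, dt, 2*dt, ...,
#'   duration`, summing to `1/dt`.
#' @examples
#' h <- hrf_double_gamma(0.1)
#' sum(h) * 0.1  # ~1
#' @export
hrf_double_gamma <- function(dt, peak_delay = 6, undershoot_delay = 16,
                             ratio = 6, duration = 32) {
  stopifnot(dt > 0, peak_delay > 0, undershoot_delay > 0, ratio > 0,
            duration > dt)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  s <- sum(h) * dt
  if (!is.finite(s) || s <= 0) {
    stop("HRF does not integrate to a finite positive value", call. = FALSE)
  }
  h / s
}

# Build the HRF from a laminar model's hrf_params list.
model_hrf <- function(model, dt) {
  p <- model$hrf_params
  hrf_double_gamma(dt,
                   peak_delay = p$peak_delay,
                   undershoot_delay = p$undershoot_delay,
                   ratio = p$ratio,
                   duration = p$duration %||% 32)
}
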