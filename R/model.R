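#' Laminar BOLD ground-truth model
#'
#' Defines the forward model used by the simulator: a depth grid between the
#' gray/white border (normalized depth 0) and the pial surface (depth 1), a
#' local hemodynamic response amplitude per depth, draining weights that mix
#' responses from deeper depths into more superficial ones, and the HRF
#' parameters of the local hemodynamic transform.
#'
#' `drain_weights_alt` optionally maps stimulus durations (as names, e.g.
#' `"10.4"`) to alternative draining-weight vectors, used only to simulate
#' duration-dependent draining. Note that because every depth shares one
#' temporal response shape per duration in this model, weight-only changes
#' rescale amplitudes without changing shape, and are therefore invisible to
#' correlation-based additivity statistics (see the package vignette).
#'
#' @param n_depths Number of simulated depths. Default 5.
#' @param depth_values Normalized depth per grid point in `[0, 1]`, ascending.
#'   Default: bin centers `(i - 0.5) / n_depths`.
#' @param local_amplitude Local response gain per depth (percent BOLD for a
#'   sustained stimulus, before draining). Default rises toward the surface.
#' @param drain_weights Non-negative draining weights per source depth.
#'   Default 1 at every depth, which roughly doubles the superficial
#'   amplitude relative to the deepest depth at 5 depths.
#' @param drain_weights_alt Optional named list of per-duration draining
#'   weight vectors (see Details).
#' @param hrf_params List with `peak_delay`, `undershoot_delay`, `ratio`, and
#'   optionally `duration` (kernel support, seconds).
#' @return A `laminar_model` object.
#' @examples
#' m <- laminar_model()
#' m$depth_values
#' @export
laminar_model <- function(n_depths = 5,
                          depth_values = NULL,
                          local_amplitude = NULL,
                          drain_weights = NULL,
                          drain_weights_alt = NULL,
                          hrf_params = list(peak_delay = 6,
                                            undershoot_delay = 16,
                                            ratio = 6,
                                            duration = 32)) {
  stopifnot(n_depths >= 1)
  depth_values <- depth_values %||% ((seq_len(n_depths) - 0.5) / n_depths)
  local_amplitude <- local_amplitude %||% seq(1, 1.4, length.out = n_depths)
  drain_weights <- drain_weights %||% rep(1, n_depths)
  stopifnot(length(depth_values) == n_depths,
            length(local_amplitude) == n_depths,
            length(drain_weights) == n_depths)
  if (any(!is.finite(depth_values)) || any(depth_values < 0) ||
      any(depth_values > 1) || is.unsorted(depth_values)) {
    stop("depth_values must be ascending and within [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(drain_weights)) || any(drain_weights < 0)) {
    stop("drain weights must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(drain_weights_alt)) {
    stopifnot(is.list(drain_weights_alt), !is.null(names(drain_weights_alt)))
    for (w in drain_weights_alt) {
      if (length(w) != n_depths || any(!is.finite(w)) || any(w < 0)) {
        stop("each drain_weights_alt entry must be a non-negative vector of length n_depths",
             call. = FALSE)
      }
    }
  }
  stopifnot(is.list(hrf_params),
            all(c("peak_delay", "undershoot_delay", "ratio") %in% names(hrf_params)))
  structure(list(n_depths = n_depths,
                 depth_values = depth_values,
                 local_amplitude = local_amplitude,
                 drain_weights = drain_weights,
                 drain_weights_alt = drain_weights_alt,
                 hrf_params = hrf_params),
            class = "laminar_model")
}

#' @export
print.laminar_model <- function(x, ...) {
  cat(sprintf("Laminar model: %d depths (%.2f-%.2f), amplitudes %s %%BOLD\n",
              x$n_depths, min(x$depth_values), max(x$depth_values),
              paste(format(x$local_amplitude, digits = 3), collapse = "/")))
  invisible(x)
}

#' Noise specification for the simulator
#'
#' Describes the additive noise applied to raw-unit series: a polynomial
#' drift plus serially correlated (AR(1)) Gaussian noise.
#'
#' @param sigma Standard deviation of the AR(1) innovations, in percent-BOLD
#'   units (1 unit of raw signal at the default baseline of 100). Default 0.
#' @param ar1 Lag-1 autocorrelation of the noise, in `[0, 1)`. Default 0.
#' @param drift_coeffs Polynomial drift coefficients `c0, c1, ...` (up to
#'   degree 4) applied to time scaled to `[-1, 1]` over the run, in raw units.
#'   Default no drift.
#' @param seed Integer seed making the noise reproducible.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sigma = 0, ar1 = 0, drift_coeffs = 0, seed = 1) {
  stopifnot(sigma >= 0, ar1 >= 0, ar1 < 1, length(drift_coeffs) <= 5,
            all(is.finite(drift_coeffs)))
  structure(list(sigma = sigma, ar1 = ar1, drift_coeffs = drift_coeffs,
                 seed = seed),
            class = "noise_spec")
}
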