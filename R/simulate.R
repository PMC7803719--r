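#' Boxcar neuronal drive for a stimulus design
#'
#' Renders the stimulus schedule as a binary drive signal per run: 1 during
#' stimulus blocks, 0 elsewhere, on a regular `dt` grid. Onsets and durations
#' must lie on the grid (after jitter they do by construction when the jitter
#' equals `dt`).
#'
#' @param design A `stimulus_design`.
#' @param dt Sampling step in seconds. Default: the design's grid step.
#' @param blocks Optional subset of `design$blocks` to render (used internally
#'   to split the drive by stimulus duration).
#' @return Matrix of 0/1 with one row per run and `round(run_length / dt)`
#'   columns.
#' @examples
#' d <- make_design(seed = 1)
#' drv <- neuronal_drive(d)
#' sum(drv[1, ]) * d$dt  # total stimulation seconds in run 1
#' @export
neuronal_drive <- function(design, dt = design$dt, blocks = design$blocks) {
  stopifnot(inherits(design, "stimulus_design"), dt > 0)
  n <- as.integer(round(design$run_length / dt))
  drive <- matrix(0, nrow = design$n_runs, ncol = n)
  if (nrow(blocks) > 0) {
    i0 <- grid_steps(blocks$onset, dt, "stimulus onset")
    len <- grid_steps(blocks$duration, dt, "stimulus duration")
    for (b in seq_len(nrow(blocks))) {
      idx <- i0[b] + seq_len(len[b])
      if (any(idx > n)) {
        stop(sprintf("block at %.1f s in run %d extends beyond the run",
                     blocks$onset[b], blocks$run[b]), call. = FALSE)
      }
      drive[blocks$run[b], idx] <- 1
    }
  }
  drive
}

#' Local hemodynamic response per depth
#'
#' Convolves a neuronal drive with the model HRF and scales by the per-depth
#' local amplitude: the hemodynamic transform of the local neuronal response
#' at each depth, before any draining. The convolution is causal; the response
#' never precedes the drive.
#'
#' @param drive Numeric drive vector for one run (dimensionless).
#' @param model A `laminar_model`.
#' @param dt Sampling step of `drive` in seconds.
#' @return Matrix (depth x time) in percent BOLD.
#' @export
local_response <- function(drive, model, dt) {
  stopifnot(inherits(model, "laminar_model"), all(is.finite(drive)), dt > 0)
  h <- model_hrf(model, dt)
  n <- length(drive)
  # direct causal convolution (exact zeros before drive onset; no FFT fuzz)
  resp <- numeric(n)
  for (k in seq_along(h)) {
    if (k > n) break
    resp[k:n] <- resp[k:n] + h[k] * drive[seq_len(n - k + 1)]
  }
  resp <- resp * dt
  out <- outer(model$local_amplitude, resp)
  rownames(out) <- sprintf("depth%02d", seq_len(model$n_depths))
  out
}

#' Apply the draining-vein mixture across cortical depth
#'
#' Discretizes the draining model: the measured response at a depth is the
#' local response plus a weighted sum of the measured responses at all deeper
#' depths (closer to the gray/white border),
#' `H[i, ] = L[i, ] + dy * sum_{j < i} w[j] * H[j, ]`, with `dy = 1/n_depths`
#' and weights indexed by the source (deeper) depth. Row 1 is the deepest
#' depth and passes through unchanged.
#'
#' @param L Matrix (depth x time) of local responses.
#' @param model A `laminar_model` supplying the weights.
#' @param weights Optional weight vector overriding `model$drain_weights`
#'   (used for per-duration draining).
#' @return Matrix (depth x time) of measured responses.
#' @export
apply_draining <- function(L, model, weights = NULL) {
  stopifnot(is.matrix(L), all(is.finite(L)))
  w <- weights %||% model$drain_weights
  if (length(w) != nrow(L)) {
    stop("drain weights length must equal the number of depths", call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("drain weights must be finite and >= 0", call. = FALSE)
  }
  n_depths <- nrow(L)
  dy <- 1 / n_depths
  H <- L
  if (n_depths > 1) {
    for (i in 2:n_depths) {
      acc <- drop(w[seq_len(i - 1)] %*% H[seq_len(i - 1), , drop = FALSE])
      H[i, ] <- L[i, ] + dy * acc
    }
  }
  H
}

#' Inject a known nonlinearity into the forward model
#'
#' Creates controlled violations of temporal additivity for power analyses.
#' Two kinds are supported: `"saturation"` compresses response amplitudes as
#' `x / (1 + strength * x)` (applied to local responses; `strength` may be a
#' per-depth vector to create depth-graded violations), and `"adaptation"`
#' decays the neuronal drive within each stimulus block as
#' `exp(-strength * t_within_block)` (applied to the drive; requires `design`).
#' `strength = 0` is the identity for both.
#'
#' @param x Drive matrix (runs x time, for adaptation) or local-response
#'   matrix (depth x time, for saturation).
#' @param kind `"saturation"` or `"adaptation"`.
#' @param strength Non-negative scalar (adaptation: 1/s decay rate;
#'   saturation: 1/percent compression), or per-depth vector for saturation.
#' @param design,dt Required for `"adaptation"`: the `stimulus_design` whose
#'   blocks define the within-block clock, and the sampling step of `x`.
#' @return Modified copy of `x`.
#' @export
inject_nonlinearity <- function(x, kind, strength, design = NULL, dt = NULL) {
  stopifnot(all(strength >= 0))
  if (all(strength == 0)) return(x)
  switch(kind,
    saturation = {
      if (is.matrix(x) && length(strength) == nrow(x)) {
        x / (1 + sweep(x, 1, strength, `*`))
      } else {
        stopifnot(length(strength) == 1L)
        x / (1 + strength * x)
      }
    },
    adaptation = {
      stopifnot(length(strength) == 1L, !is.null(design), !is.null(dt))
      drive <- if (is.matrix(x)) x else matrix(x, nrow = 1)
      b <- design$blocks
      i0 <- grid_steps(b$onset, dt, "stimulus onset")
      len <- grid_steps(b$duration, dt, "stimulus duration")
      for (k in seq_len(nrow(b))) {
        idx <- i0[k] + seq_len(len[k])
        decay <- exp(-strength * (seq_len(len[k]) - 1) * dt)
        drive[b$run[k], idx] <- drive[b$run[k], idx] * decay
      }
      if (is.matrix(x)) drive else drop(drive)
    },
    stop(sprintf("unknown nonlinearity kind: '%s'", kind), call. = FALSE)
  )
}

#' Add drift and serially correlated noise to a simulated series
#'
#' Converts a percent-BOLD series to raw scanner units around a baseline and
#' adds a polynomial drift plus AR(1) Gaussian noise:
#' `out = baseline * (1 + H/100) + drift(t) + ar1_noise(t)`. Reproducible
#' given the spec's seed; each row receives an independent noise stream.
#'
#' @param H Matrix (series x time) or vector, percent BOLD.
#' @param noise A `noise_spec`.
#' @param baseline Raw-unit baseline. Default 100, so percent and raw noise
#'   units coincide.
#' @return Same shape as `H`, raw units.
#' @export
add_noise <- function(H, noise, baseline = 100) {
  stopifnot(inherits(noise, "noise_spec"))
  vec <- !is.matrix(H)
  if (vec) H <- matrix(H, nrow = 1)
  n <- ncol(H)
  tt <- seq(-1, 1, length.out = n)
  drift <- rep(0, n)
  for (k in seq_along(noise$drift_coeffs)) {
    drift <- drift + noise$drift_coeffs[k] * tt^(k - 1)
  }
  out <- baseline * (1 + H / 100) + matrix(drift, nrow = nrow(H), ncol = n,
                                           byrow = TRUE)
  if (noise$sigma > 0) {
    eps <- with_seed(noise$seed, {
      t(vapply(seq_len(nrow(H)), function(i) {
        if (noise$ar1 > 0) {
          as.numeric(stats::arima.sim(model = list(ar = noise$ar1), n = n,
                                      sd = noise$sigma))
        } else {
          stats::rnorm(n, 0, noise$sigma)
        }
      }, numeric(n)))
    })
    out <- out + eps
  }
  if (vec) drop(out) else out
}

#' Simulate noise-free laminar depth time series
#'
#' Runs the full forward model for every run of a design: neuronal drive,
#' optional nonlinearity, local hemodynamic responses, and the draining
#' mixture across depth. When the model carries per-duration draining weights
#' (`drain_weights_alt`), the drive is split by stimulus duration and each
#' duration class is drained with its own weights before summation; with
#' identical weights this reduces exactly to the single-pass model (linearity
#' of the draining recursion).
#'
#' @param design A `stimulus_design`.
#' @param model A `laminar_model`.
#' @param dt Simulation step in seconds. Default: the design grid step.
#' @param nonlinearity Optional list with `kind` and `strength` (see
#'   [inject_nonlinearity()]).
#' @return List with one matrix (depth x time, percent BOLD) per run.
#' @export
simulate_depth_series <- function(design, model, dt = design$dt,
                                  nonlinearity = NULL) {
  stopifnot(inherits(design, "stimulus_design"), inherits(model, "laminar_model"))
  nl_kind <- nonlinearity$kind
  nl_strength <- nonlinearity$strength %||% 0

  duration_groups <- if (is.null(model$drain_weights_alt)) {
    list(all = list(blocks = design$blocks, weights = model$drain_weights))
  } else {
    durs <- sort(unique(design$blocks$duration))
    stats::setNames(lapply(durs, function(d) {
      list(blocks = design$blocks[design$blocks$duration == d, , drop = FALSE],
           weights = model$drain_weights_alt[[dur_key(d)]] %||% model$drain_weights)
    }), dur_key(durs))
  }

  lapply(seq_len(design$n_runs), function(r) {
    H <- NULL
    for (g in duration_groups) {
      drive <- neuronal_drive(design, dt, blocks = g$blocks)[r, ]
      if (!is.null(nl_kind) && nl_kind == "adaptation") {
        sub <- design
        sub$blocks <- g$blocks[g$blocks$run == r, , drop = FALSE]
        sub$blocks$run <- 1L
        sub$n_runs <- 1L
        drive <- inject_nonlinearity(matrix(drive, nrow = 1), "adaptation",
                                     nl_strength, design = sub, dt = dt)[1, ]
      }
      L <- local_response(drive, model, dt)
      if (!is.null(nl_kind) && nl_kind == "saturation") {
        L <- inject_nonlinearity(L, "saturation", nl_strength)
      }
      Hg <- apply_draining(L, model, weights = g$weights)
      H <- if (is.null(H)) Hg else H + Hg
    }
    H
  })
}
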