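# Shared fixtures, built in code at test time.

# Design with inter-block gaps wide enough (~35 s) that no trial window
# overlaps a neighboring block's response when the HRF support is <= 15.6 s.
clean_design <- function(n_runs = 8, seed = 3) {
  make_design(n_runs = n_runs, reps_per_duration = 2, seed = seed)
}

# Model whose HRF support fits inside the 15.6 s post-stimulus window, so
# shift-and-sum predictions are exact by construction (no truncated tail).
window_limited_model <- function(...) {
  laminar_model(hrf_params = list(peak_delay = 6, undershoot_delay = 16,
                                  ratio = 6, duration = 15.6), ...)
}

# Per-run trial sets for one depth bin of simulated depth series.
depth_trials <- function(H_runs, design, bin, dt = 1.3, baseline = 15.6) {
  lapply(seq_along(H_runs), function(r) {
    extract_blocks(H_runs[[r]][bin, ], design, run = r, dt = dt,
                   baseline = baseline)
  })
}

# Depth-level percent-unit series with AR(1) noise added directly (no raw
# round-trip). `scale` is an optional per-depth multiplier on sigma; scaling
# noise to the depth profile of response amplitude emulates physiological
# noise that grows with signal strength, keeping SNR constant across depth so
# the depth trend of r is flat under the null. The noise field is a property
# of the acquisition: when comparing arms, compute `scale` once from the
# linear reference (see amp_noise_scale) and reuse it.
percent_noise_runs <- function(H_runs, sigma = 0.4, ar1 = 0.3, seed = 1,
                               scale = NULL) {
  sig <- sigma * (scale %||% rep(1, nrow(H_runs[[1]])))
  lapply(seq_along(H_runs), function(r) {
    H <- H_runs[[r]]
    eps <- add_noise(matrix(0, nrow(H), ncol(H)),
                     noise_spec(sigma = 1, ar1 = ar1, seed = seed + r)) - 100
    H + eps * sig
  })
}

amp_noise_scale <- function(H_runs) {
  amp <- apply(H_runs[[1]], 1, max)
  amp / mean(amp)
}

`%||%` <- laminarity:::`%||%`

# Noisy percent-unit depth-bin series: forward model -> raw units with AR(1)
# noise at the volume TR -> per-run conditioning back to percent at dt.
# Despiking is off: these series stand for already-averaged ROI/bin data,
# where acquisition spikes have no analogue (despiking is a per-voxel stage).
noisy_conditioned_runs <- function(design, model, sigma = 0.4, ar1 = 0.3,
                                   seed = 1, tr = 2.6, dt = 1.3,
                                   nonlinearity = NULL, detrend_degree = 4) {
  H <- simulate_depth_series(design, model, dt = dt,
                             nonlinearity = nonlinearity)
  step <- as.integer(round(tr / dt))
  lapply(seq_along(H), function(r) {
    idx <- seq(1, ncol(H[[r]]), by = step)
    raw <- add_noise(H[[r]][, idx, drop = FALSE],
                     noise_spec(sigma = sigma, ar1 = ar1, seed = seed + r))
    condition_run(raw, tr = tr, dt_out = dt, z_thresh = NULL,
                  detrend_degree = detrend_degree)
  })
}
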