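#' Render simulated depth series into a voxel-level dataset
#'
#' Expands per-depth laminar responses into voxels: each depth bin gets
#' `n_voxels_per_depth` voxels carrying that depth's time course, sampled at
#' the volume TR, converted to raw scanner units around a baseline of 100,
#' with independent noise per voxel. Each voxel's normalized depth is drawn
#' uniformly inside its bin's depth interval, so quantile binning of the
#' emitted depth map recovers the generating bins.
#'
#' @param H_runs List of depth x time matrices (percent BOLD) at step
#'   `dt_sim`, one per run, e.g. from [simulate_depth_series()].
#' @param model The `laminar_model` that generated `H_runs`.
#' @param n_voxels_per_depth Voxels per depth bin. Default 1.
#' @param roi_id Integer ROI label for all emitted voxels. Default 1.
#' @param noise A `noise_spec`; per-run noise streams are derived from its
#'   seed. Default: no noise.
#' @param noise_scale Optional per-depth multiplier on the noise sd (length
#'   `n_depths`). Scaling noise with the depth profile of response amplitude
#'   emulates physiological noise, which grows with signal strength and keeps
#'   the effective SNR roughly constant across depth.
#' @param design The generating `stimulus_design` (stored in the dataset).
#' @param tr Volume repetition time in seconds. Default 2.6.
#' @param dt_sim Simulation step of `H_runs` in seconds. Default 1.3.
#' @param baseline Raw-unit baseline. Default 100.
#' @return A `synthetic_dataset`: list with `series` (array run x voxel x
#'   volume, raw units), `depth_map`, `roi_labels`, `design`, `truth` (the
#'   model), `tr`.
#' @export
render_voxels <- function(H_runs, model, n_voxels_per_depth = 1, roi_id = 1L,
                          noise = noise_spec(), design = NULL, tr = 2.6,
                          dt_sim = 1.3, baseline = 100, noise_scale = NULL) {
  stopifnot(n_voxels_per_depth >= 1, inherits(model, "laminar_model"))
  step <- grid_steps(tr, dt_sim, "volume TR")
  n_runs <- length(H_runs)
  n_sim <- ncol(H_runs[[1]])
  vol_idx <- seq(1, n_sim, by = step)
  n_vol <- length(vol_idx)
  n_depths <- model$n_depths
  n_vox <- n_depths * n_voxels_per_depth
  depth_bin <- rep(seq_len(n_depths), each = n_voxels_per_depth)

  depth_map <- with_seed(noise$seed, {
    stats::runif(n_vox, (depth_bin - 1) / n_depths, depth_bin / n_depths)
  })

  if (!is.null(noise_scale)) stopifnot(length(noise_scale) == n_depths)
  series <- array(NA_real_, dim = c(n_runs, n_vox, n_vol))
  for (r in seq_len(n_runs)) {
    Hv <- H_runs[[r]][depth_bin, vol_idx, drop = FALSE]
    run_noise <- noise
    run_noise$seed <- noise$seed + r
    if (is.null(noise_scale) || noise$sigma == 0) {
      series[r, , ] <- add_noise(Hv, run_noise, baseline = baseline)
    } else {
      clean_noise <- run_noise
      clean_noise$sigma <- 0
      unit_noise <- run_noise
      unit_noise$sigma <- 1
      unit_noise$drift_coeffs <- 0
      eps <- add_noise(matrix(0, n_vox, n_vol), unit_noise,
                       baseline = 0)
      series[r, , ] <- add_noise(Hv, clean_noise, baseline = baseline) +
        eps * (noise$sigma * noise_scale[depth_bin])
    }
  }

  structure(list(series = series,
                 depth_map = depth_map,
                 roi_labels = rep(as.integer(roi_id), n_vox),
                 design = design,
                 truth = model,
                 tr = tr),
            class = "synthetic_dataset")
}

# Concatenate voxel-level datasets (same design/runs/volumes) along voxels.
bind_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  if (length(datasets) == 1) return(datasets[[1]])
  d1 <- datasets[[1]]
  series <- do.call(abind_vox, lapply(datasets, `[[`, "series"))
  structure(list(series = series,
                 depth_map = unlist(lapply(datasets, `[[`, "depth_map")),
                 roi_labels = unlist(lapply(datasets, `[[`, "roi_labels")),
                 design = d1$design,
                 truth = lapply(datasets, `[[`, "truth"),
                 tr = d1$tr),
            class = "synthetic_dataset")
}

# Bind run x voxel x time arrays along the voxel axis.
abind_vox <- function(...) {
  arrs <- list(...)
  n_runs <- dim(arrs[[1]])[1]
  n_vol <- dim(arrs[[1]])[3]
  total <- sum(vapply(arrs, function(a) dim(a)[2], integer(1)))
  out <- array(NA_real_, dim = c(n_runs, total, n_vol))
  at <- 0
  for (a in arrs) {
    out[, at + seq_len(dim(a)[2]), ] <- a
    at <- at + dim(a)[2]
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  d <- dim(x$series)
  cat(sprintf("Synthetic laminar dataset: %d runs x %d voxels x %d volumes (TR %.1f s), %d ROI(s)\n",
              d[1], d[2], d[3], x$tr, length(unique(x$roi_labels))))
  invisible(x)
}
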