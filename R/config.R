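# Configuration handling: flat key-value configs with strict key validation.

sim_config_defaults <- function() {
  list(
    n_runs = 8L,
    n_volumes = 102L,
    tr = 2.6,
    dt = 1.3,
    durations = c(2.6, 5.2, 10.4),
    reps_per_duration = 4L,
    rest_mean = 15.6,
    jitter = 1.3,
    n_depths = 5L,
    n_voxels_per_depth = 40L,
    rois = c(V1 = 1L, V2 = 2L, V3 = 3L),
    roi_gains = c(V1 = 1.0, V2 = 0.95, V3 = 1.05),
    local_amplitude = NULL,     # default set by laminar_model()
    drain_weights = NULL,       # default set by laminar_model()
    hrf_peak_delay = 6,
    hrf_undershoot_delay = 16,
    hrf_ratio = 6,
    hrf_duration = 32,
    sigma = 4,
    ar1 = 0.3,
    noise_amp_scale = TRUE,
    drift_coeffs = c(0, 1.5, -1, 0.8, 0.5),
    nonlinearity_kind = "none",
    nonlinearity_strength = 0
  )
}

analysis_config_defaults <- function() {
  list(
    series = NULL,              # character vector of per-run 4D NIfTI paths
    depth_map = NULL,           # 3D NIfTI path
    roi_mask = NULL,            # 3D integer-labeled NIfTI path
    design = NULL,              # design TSV path
    run_length = NULL,          # seconds; defaults to n_volumes * tr on read
    tr = 2.6,
    dt_out = 1.3,
    despike_z = 5,              # NA/NULL disables despiking
    detrend_degree = 4L,
    n_bins = 5L,
    baseline = 15.6,
    alpha = 0.05,
    roi_names = c(V1 = 1L, V2 = 2L, V3 = 3L)
  )
}

# Merge user values into defaults, rejecting unknown keys.
merge_config <- function(user, defaults, what) {
  user <- user %||% list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown %s config key(s): %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(user)] <- user
  defaults
}

#' Read a pipeline configuration file
#'
#' Configs are flat key-value YAML. Named vectors (e.g. ROI label maps) are
#' written as YAML maps. Unknown keys are rejected at merge time.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  # YAML maps arrive as lists; flatten the named ones we expect as vectors
  for (key in c("rois", "roi_gains", "roi_names")) {
    if (!is.null(cfg[[key]])) cfg[[key]] <- unlist(cfg[[key]])
  }
  for (key in c("durations", "drift_coeffs", "local_amplitude", "drain_weights",
                "series")) {
    if (!is.null(cfg[[key]])) cfg[[key]] <- unlist(cfg[[key]])
  }
  cfg
}
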