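test_that("local response is a causal, linear convolution with the HRF", {
  m <- laminar_model()
  d <- make_design(n_runs = 1, durations = 2.6, reps_per_duration = 1,
                   jitter = 0, seed = 1)
  drive <- neuronal_drive(d)[1, ]

  expect_true(all(local_response(rep(0, 100), m, 1.3) == 0))

  L <- local_response(drive, m, 1.3)
  m2 <- m
  m2$local_amplitude <- 2 * m$local_amplitude
  expect_equal(local_response(drive, m2, 1.3), 2 * L, tolerance = 1e-12)

  # impulse drive reproduces the sampled HRF per depth (scaled by dt)
  imp <- c(1, rep(0, 49))
  Li <- local_response(imp, m, 1.3)
  h_pad <- c(hrf_double_gamma(1.3), rep(0, 50))[1:50]
  for (dep in c(1, 3, 5)) {
    expect_equal(Li[dep, ], m$local_amplitude[dep] * 1.3 * h_pad,
                 tolerance = 1e-12)
  }
  # causality: no response before the drive turns on
  onset_idx <- which(drive == 1)[1]
  expect_true(all(L[, seq_len(onset_idx - 1)] == 0))
})

test_that("draining recursion matches a direct linear-system solve", {
  set.seed(42)
  for (rep in 1:5) {
    n_dep <- sample(2:6, 1)
    L <- matrix(abs(rnorm(n_dep * 30)), n_dep)
    w <- runif(n_dep, 0, 2)
    m <- laminar_model(n_depths = n_dep, drain_weights = w)
    H <- apply_draining(L, m)
    # independent oracle: H = (I - dy * W)^{-1} L with strictly lower
    # triangular W[i, j] = w[j]
    W <- matrix(0, n_dep, n_dep)
    for (i in seq_len(n_dep)) for (j in seq_len(n_dep)) {
      if (j < i) W[i, j] <- w[j]
    }
    H_direct <- solve(diag(n_dep) - W / n_dep, L)
    expect_equal(H, H_direct, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("draining edge cases: null weights, single depth, negative weights", {
  L <- matrix(runif(40), 4)
  m <- laminar_model(n_depths = 4, drain_weights = rep(0, 4))
  expect_equal(apply_draining(L, m), L, ignore_attr = TRUE)

  L1 <- matrix(runif(10), 1)
  m1 <- laminar_model(n_depths = 1)
  expect_equal(apply_draining(L1, m1), L1, ignore_attr = TRUE)

  m4 <- laminar_model(n_depths = 4)
  expect_error(apply_draining(L, m4, weights = c(1, -1, 1, 1)), ">= 0")
  expect_error(laminar_model(n_depths = 2, drain_weights = c(-0.1, 1)), ">= 0")
})

test_that("peak response is non-decreasing toward the surface under draining", {
  d <- make_design(seed = 4)
  m <- laminar_model(local_amplitude = rep(1, 5))  # isolate the draining effect
  H <- simulate_depth_series(d, m)
  for (r in seq_along(H)) {
    peaks <- apply(H[[r]], 1, max)
    expect_true(all(diff(peaks) >= -1e-12))
  }
})

test_that("forward model is additive: a 5.2 s response is the shifted sum of 2.6 s responses", {
  base <- make_design(n_runs = 1, durations = 2.6, reps_per_duration = 1,
                      jitter = 0, seed = 9)
  m <- laminar_model()
  H26 <- simulate_depth_series(base, m)[[1]]
  d52 <- base
  d52$blocks$duration <- 5.2
  H52 <- simulate_depth_series(d52, m)[[1]]
  shift <- as.integer(2.6 / 1.3)
  n <- ncol(H26)
  H26_shifted <- cbind(matrix(0, nrow(H26), shift), H26[, 1:(n - shift)])
  expect_equal(H52, H26 + H26_shifted, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("per-duration draining weights reduce to the single-pass model when equal", {
  d <- make_design(n_runs = 2, seed = 6)
  m <- laminar_model()
  m_alt <- laminar_model(drain_weights_alt = list(
    `2.6` = m$drain_weights, `5.2` = m$drain_weights, `10.4` = m$drain_weights))
  H <- simulate_depth_series(d, m)
  H_alt <- simulate_depth_series(d, m_alt)
  expect_equal(H, H_alt, tolerance = 1e-10)
})

test_that("noise model: exact affine at sigma 0, seeded, with AR(1) stationary variance", {
  H <- matrix(runif(60), 3)
  ns0 <- noise_spec(sigma = 0, seed = 1)
  expect_equal(add_noise(H, ns0), 100 * (1 + H / 100), ignore_attr = TRUE)

  ns <- noise_spec(sigma = 2, ar1 = 0.4, drift_coeffs = c(1, 2, -1), seed = 7)
  a <- add_noise(H, ns)
  b <- add_noise(H, ns)
  expect_identical(a, b)
  expect_false(identical(a, add_noise(H, noise_spec(sigma = 2, ar1 = 0.4,
                                                    drift_coeffs = c(1, 2, -1),
                                                    seed = 8))))

  # stationary sd of pure AR(1) noise ~ sigma / sqrt(1 - ar1^2) at 1e5 samples
  sigma <- 1.5; phi <- 0.6
  pure <- add_noise(matrix(0, 1, 1e5), noise_spec(sigma = sigma, ar1 = phi,
                                                  seed = 3)) - 100
  expect_equal(sd(pure), sigma / sqrt(1 - phi^2), tolerance = 0.05)
})

test_that("nonlinearity injection: identity at zero strength, adaptation decays within blocks", {
  d <- make_design(n_runs = 1, seed = 2)
  drive <- neuronal_drive(d)
  expect_identical(inject_nonlinearity(drive, "adaptation", 0,
                                       design = d, dt = 1.3), drive)
  L <- matrix(runif(50), 5)
  expect_identical(inject_nonlinearity(L, "saturation", 0), L)

  adapted <- inject_nonlinearity(drive, "adaptation", 1.0, design = d, dt = 1.3)
  b <- d$blocks[d$blocks$duration == 10.4, ][1, ]
  i0 <- as.integer(round(b$onset / 1.3))
  len <- as.integer(round(10.4 / 1.3))
  expect_lt(adapted[1, i0 + len], adapted[1, i0 + 1])
  expect_equal(adapted[1, i0 + 1], 1)  # block start undecayed

  # per-depth saturation strengths compress superficial depths more
  Lpos <- matrix(1, 3, 4)
  sat <- inject_nonlinearity(Lpos, "saturation", c(0, 0.5, 1))
  expect_equal(sat[1, 1], 1)
  expect_true(all(diff(sat[, 1]) < 0))

  expect_error(inject_nonlinearity(L, "quadratic", 1), "unknown nonlinearity")
})

test_that("rendered voxels carry their depth bin's series and recover the bins", {
  d <- clean_design(n_runs = 2)
  m <- laminar_model()
  H <- simulate_depth_series(d, m)
  ds <- render_voxels(H, m, n_voxels_per_depth = 1, roi_id = 1,
                      noise = noise_spec(sigma = 0, seed = 1), design = d)
  idx <- seq(1, ncol(H[[1]]), by = 2)
  for (dep in 1:5) {
    expect_equal(ds$series[1, dep, ], 100 * (1 + H[[1]][dep, idx] / 100),
                 tolerance = 1e-12)
  }

  # quantile binning of the emitted depth map recovers the generating bins
  ds2 <- render_voxels(H, m, n_voxels_per_depth = 17, roi_id = 1,
                       noise = noise_spec(sigma = 0, seed = 5), design = d)
  bins <- depth_quantile_bins(ds2$depth_map, rep(TRUE, 85), n_bins = 5)
  expect_equal(bins$assignment, rep(1:5, each = 17))
})

test_that("identical seeds and configs give bit-identical synthetic datasets", {
  cfg <- list(n_voxels_per_depth = 2L, n_runs = 2L)
  a <- simulate_study(cfg, seed = 21)
  b <- simulate_study(cfg, seed = 21)
  expect_identical(a$series, b$series)
  expect_identical(a$depth_map, b$depth_map)
  expect_false(identical(a$series, simulate_study(cfg, seed = 22)$series))
})
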