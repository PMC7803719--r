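test_that("shift-and-sum prediction shifts by the source duration", {
  # impulse response, 2-sample shift, k = 2 -> unit mass at samples 0 and 2
  pred <- shift_sum_predict(c(1, 0, 0, 0), source = 2, target = 4, dt = 1)
  expect_equal(pred, c(1, 0, 1, 0, 0, 0))

  # short->medium at the study grid: one copy shifted by 2.6 s plus the original
  r26 <- rnorm(14)
  p <- shift_sum_predict(r26, 2.6, 5.2, dt = 1.3)
  expect_length(p, 16)
  expect_equal(p, c(r26, 0, 0) + c(0, 0, r26))

  expect_error(shift_sum_predict(r26, 2.6, 6.6, dt = 1.3), "integer multiple")
  expect_error(shift_sum_predict(r26, 3, 6, dt = 1.3), "grid")
})

test_that("predicting long from short composes through the medium duration", {
  set.seed(8)
  r26 <- rnorm(14)
  direct <- shift_sum_predict(r26, 2.6, 10.4, dt = 1.3)
  via_52 <- shift_sum_predict(shift_sum_predict(r26, 2.6, 5.2, dt = 1.3),
                              5.2, 10.4, dt = 1.3)
  expect_equal(direct, via_52, tolerance = 1e-12)
})

test_that("split enumeration is exhaustive, ordered, and errors on bad k", {
  s84 <- enumerate_splits(8, 4)
  expect_length(s84, 70)
  expect_equal(s84[[1]]$train, 1:4)
  expect_equal(s84[[1]]$test, 5:8)
  # every split partitions the runs
  for (s in s84) expect_equal(sort(c(s$train, s$test)), 1:8)
  # no duplicated train sets
  keys <- vapply(s84, function(s) paste(s$train, collapse = ","), character(1))
  expect_equal(anyDuplicated(keys), 0L)

  expect_length(enumerate_splits(2, 1), 2)

  # brute-force oracle for (4, 2): enumerate subsets by bit mask
  masks <- Filter(function(m) sum(bitwAnd(m, 2^(0:3)) > 0) == 2, 0:15)
  oracle <- sort(vapply(masks, function(m) {
    paste(which(bitwAnd(m, 2^(0:3)) > 0), collapse = ",")
  }, character(1)))
  got <- sort(vapply(enumerate_splits(4, 2),
                     function(s) paste(s$train, collapse = ","), character(1)))
  expect_equal(got, oracle)

  expect_error(enumerate_splits(4, 4), "0 < k < n_runs")
  expect_error(enumerate_splits(4, 0), "0 < k < n_runs")
})

test_that("noise-free linear data give r = 1 for every split, depth, and condition", {
  d <- clean_design()
  m <- window_limited_model()
  H <- simulate_depth_series(d, m)
  for (bin in 1:5) {
    trials <- depth_trials(H, d, bin)
    res <- additivity_test(trials)
    expect_equal(res$median_r, rep(1, 3), tolerance = 1e-9)
    expect_equal(res$ceiling_r, rep(1, 3), tolerance = 1e-9)
    expect_true(all(abs(attr(res, "splits_r") - 1) < 1e-9))
    expect_equal(res$n_splits, rep(70, 3))
  }
})

test_that("orthogonal observations give r near 0 and identical splits share the median", {
  set.seed(12)
  src <- rnorm(14)
  pred <- shift_sum_predict(src, 2.6, 5.2, dt = 1.3)
  # observation orthogonalized against the centered prediction
  raw <- rnorm(16)
  pc <- pred - mean(pred)
  obs <- raw - mean(raw) - sum(raw * pc) / sum(pc^2) * pc
  mk <- function() {
    structure(list(`2.6` = rbind(src), `5.2` = rbind(obs)),
              durations = c(2.6, 5.2), dt = 1.3, baseline = 15.6,
              class = "trial_set")
  }
  trials <- list(mk(), mk(), mk(), mk())
  cv <- crossval_correlation(trials, list(source = 2.6, target = 5.2))
  expect_lt(abs(cv$median_r), 1e-9)
  # all splits identical -> median equals the common per-split value
  expect_true(all(abs(cv$r - cv$r[1]) < 1e-12))
})

test_that("Pearson scoring is invariant to positive scaling of the source response", {
  d <- clean_design(n_runs = 4)
  m <- laminar_model()
  H <- simulate_depth_series(d, m)
  noisy <- lapply(H, function(h) h + matrix(rnorm(length(h), 0, 0.2),
                                            nrow(h)))
  trials <- depth_trials(noisy, d, bin = 2)
  scaled <- lapply(trials, function(ts) {
    ts[["2.6"]] <- 7.3 * ts[["2.6"]]
    ts
  })
  cv1 <- crossval_correlation(trials, list(source = 2.6, target = 10.4))
  cv2 <- crossval_correlation(scaled, list(source = 2.6, target = 10.4))
  expect_equal(cv1$r, cv2$r, tolerance = 1e-12)
})

test_that("zero-variance splits are excluded with a warning; all-excluded errors", {
  flat <- structure(list(`2.6` = rbind(rep(1, 14)), `5.2` = rbind(rep(2, 16))),
                    durations = c(2.6, 5.2), dt = 1.3, baseline = 15.6,
                    class = "trial_set")
  set.seed(2)
  lively <- structure(list(`2.6` = rbind(rnorm(14)), `5.2` = rbind(rnorm(16))),
                      durations = c(2.6, 5.2), dt = 1.3, baseline = 15.6,
                      class = "trial_set")
  expect_warning(
    cv <- crossval_correlation(list(lively, flat),
                               list(source = 2.6, target = 5.2),
                               splits = enumerate_splits(2, 1)),
    "excluded")
  expect_equal(cv$n_splits, 1)
  expect_error(
    suppressWarnings(crossval_correlation(list(flat, flat),
                                          list(source = 2.6, target = 5.2),
                                          splits = enumerate_splits(2, 1))),
    "all splits excluded")
})

test_that("noise ceiling hits +1 and -1 on identical and sign-flipped halves", {
  set.seed(6)
  base <- rnorm(20)
  mk <- function(v) structure(list(`10.4` = rbind(v)), durations = 10.4,
                              dt = 1.3, baseline = 15.6, class = "trial_set")
  same <- list(mk(base), mk(base))
  expect_equal(noise_ceiling(same, 10.4, enumerate_splits(2, 1))$median_r, 1)
  flipped <- list(mk(base), mk(-base))
  expect_equal(noise_ceiling(flipped, 10.4, enumerate_splits(2, 1))$median_r, -1)
})

test_that("the noise ceiling bounds the cross-validated fit in expectation", {
  # paired noisy simulations; one-sided sign test that ceiling >= prediction r
  d <- make_design(n_runs = 4, seed = 17)
  m <- laminar_model()
  wins <- 0L
  n_seed <- 100
  for (s in seq_len(n_seed)) {
    runs <- noisy_conditioned_runs(d, m, sigma = 0.4, ar1 = 0.3, seed = 1000 + s)
    trials <- lapply(seq_along(runs), function(r) {
      extract_blocks(runs[[r]][3, ], d, run = r)
    })
    splits <- enumerate_splits(4, 2)
    cv <- crossval_correlation(trials, list(source = 2.6, target = 10.4), splits)
    nc <- noise_ceiling(trials, 10.4, splits)
    if (nc$median_r >= cv$median_r) wins <- wins + 1L
  }
  expect_lt(binom.test(wins, n_seed, p = 0.5, alternative = "greater")$p.value,
            0.05)
})

test_that("adaptation nonlinearity lowers the long-duration prediction fit at every depth", {
  d <- clean_design()
  m <- window_limited_model()
  H_lin <- simulate_depth_series(d, m)
  H_nl <- simulate_depth_series(d, m,
                                nonlinearity = list(kind = "adaptation",
                                                    strength = 0.3))
  for (bin in 1:5) {
    cv_lin <- crossval_correlation(depth_trials(H_lin, d, bin),
                                   list(source = 2.6, target = 10.4))
    cv_nl <- crossval_correlation(depth_trials(H_nl, d, bin),
                                  list(source = 2.6, target = 10.4))
    expect_lt(cv_nl$median_r, cv_lin$median_r)
  }
})
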