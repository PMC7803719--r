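#' Shift-and-sum prediction of a longer-duration response
#'
#' Predicts the response to a stimulus of duration `target` from the mean
#' response to a stimulus of duration `source` by adding `k = target/source`
#' copies of the source response, each shifted by a multiple of the source
#' duration. The source response (stimulus + post-stimulus baseline window)
#' is zero-padded on the right, i.e. assumed returned to baseline beyond its
#' window.
#'
#' @param response Numeric mean trial response for the source duration,
#'   length `(source + baseline) / dt`.
#' @param source,target Stimulus durations in seconds; `target` must be an
#'   integer multiple (>= 2) of `source`.
#' @param dt Sampling step in seconds.
#' @return Predicted response of length `length(response) +
#'   (target - source) / dt`.
#' @examples
#' shift_sum_predict(c(1, 0, 0, 0), source = 2, target = 4, dt = 1)
#' @export
shift_sum_predict <- function(response, source, target, dt) {
  stopifnot(source > 0, target > source, dt > 0)
  k <- target / source
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("target duration %.3g s is not an integer multiple of source %.3g s",
                 target, source), call. = FALSE)
  }
  k <- as.integer(round(k))
  shift <- grid_steps(source, dt, "shift")
  out_len <- length(response) + (k - 1L) * shift
  padded <- c(response, rep(0, out_len - length(response)))
  pred <- numeric(out_len)
  for (i in 0:(k - 1L)) {
    shifted <- c(rep(0, i * shift), padded)[seq_len(out_len)]
    pred <- pred + shifted
  }
  pred
}

#' Enumerate all split-half train/test partitions of runs
#'
#' Lists every choice of `k` training runs out of `n_runs`, with the
#' complement as test set, in deterministic lexicographic order. Train and
#' test roles are distinct, so 8 runs split 4+4 give `choose(8, 4) = 70`
#' ordered splits.
#'
#' @param n_runs Total number of runs. Default 8.
#' @param k Training runs per split. Default 4.
#' @return List of `choose(n_runs, k)` elements, each a list with integer
#'   vectors `train` and `test`.
#' @examples
#' length(enumerate_splits(8, 4))  # 70
#' @export
enumerate_splits <- function(n_runs = 8, k = 4) {
  if (k <= 0 || k >= n_runs) {
    stop("k must satisfy 0 < k < n_runs", call. = FALSE)
  }
  combos <- utils::combn(n_runs, k)
  lapply(seq_len(ncol(combos)), function(j) {
    tr <- combos[, j]
    list(train = tr, test = setdiff(seq_len(n_runs), tr))
  })
}

# Mean trial response of one duration pooled over the given runs.
mean_response <- function(trials_by_run, duration, runs) {
  mats <- lapply(trials_by_run[runs], `[[`, dur_key(duration))
  colMeans(do.call(rbind, mats))
}

#' Cross-validated correlation of shift-and-sum predictions
#'
#' For each split: averages the source-duration trials of the training runs,
#' builds the shift-and-sum prediction for the target duration, and
#' correlates it (Pearson, over the full target window) with the mean
#' observed target-duration response of the test runs. The median over
#' splits is the summary statistic.
#'
#' @param trials_by_run List with one `trial_set` per run (a single ROI/depth
#'   bin), e.g. from [extract_blocks()].
#' @param condition List with `source` and `target` durations in seconds.
#' @param splits Splits from [enumerate_splits()]. Default: all split-half
#'   partitions of the available runs.
#' @param dt Sampling step in seconds (taken from the trials when present).
#' @return List with `median_r`, `r` (per-split vector, `NA` for excluded
#'   splits), and `n_splits` (number of splits entering the median).
#'   Zero-variance splits are excluded with a warning; if all splits are
#'   excluded an error is raised.
#' @export
crossval_correlation <- function(trials_by_run, condition, splits = NULL,
                                 dt = attr(trials_by_run[[1]], "dt") %||% 1.3) {
  n_runs <- length(trials_by_run)
  splits <- splits %||% enumerate_splits(n_runs, n_runs %/% 2)
  r <- vapply(splits, function(s) {
    src <- mean_response(trials_by_run, condition$source, s$train)
    pred <- shift_sum_predict(src, condition$source, condition$target, dt)
    obs <- mean_response(trials_by_run, condition$target, s$test)
    if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
    stats::cor(pred, obs)
  }, numeric(1))
  if (anyNA(r)) {
    if (all(is.na(r))) {
      stop("all splits excluded: zero-variance predictions or observations",
           call. = FALSE)
    }
    warning(sprintf("%d split(s) excluded due to zero variance", sum(is.na(r))),
            call. = FALSE)
  }
  list(median_r = stats::median(r, na.rm = TRUE), r = r,
       n_splits = sum(!is.na(r)))
}

#' Split-half noise ceiling of an observed response
#'
#' For each split: correlates the mean observed response of one half of the
#' runs with that of the other half, for a single stimulus duration. The
#' median over splits estimates the best correlation any prediction could
#' achieve given the measurement noise.
#'
#' @inheritParams crossval_correlation
#' @param duration Stimulus duration in seconds.
#' @return List with `median_r`, `r`, `n_splits` as in
#'   [crossval_correlation()].
#' @export
noise_ceiling <- function(trials_by_run, duration, splits = NULL) {
  n_runs <- length(trials_by_run)
  splits <- splits %||% enumerate_splits(n_runs, n_runs %/% 2)
  r <- vapply(splits, function(s) {
    a <- mean_response(trials_by_run, duration, s$train)
    b <- mean_response(trials_by_run, duration, s$test)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (anyNA(r)) {
    if (all(is.na(r))) {
      stop("all splits excluded: zero-variance observations", call. = FALSE)
    }
    warning(sprintf("%d split(s) excluded due to zero variance", sum(is.na(r))),
            call. = FALSE)
  }
  list(median_r = stats::median(r, na.rm = TRUE), r = r,
       n_splits = sum(!is.na(r)))
}

#' Default prediction conditions for a duration set
#'
#' All ordered pairs where the target is a longer integer multiple of the
#' source: at the default durations, short-to-medium, short-to-long, and
#' medium-to-long.
#'
#' @param durations Stimulus durations in seconds.
#' @return data.frame with columns `source`, `target`, `label`.
#' @export
default_conditions <- function(durations = c(2.6, 5.2, 10.4)) {
  grid <- expand.grid(source = durations, target = durations)
  grid <- grid[grid$target > grid$source &
                 abs(grid$target / grid$source -
                       round(grid$target / grid$source)) < 1e-9, ]
  grid <- grid[order(grid$source, grid$target), ]
  grid$label <- sprintf("%.3g->%.3g", grid$source, grid$target)
  rownames(grid) <- NULL
  grid
}

#' Temporal-additivity test for one ROI/depth bin
#'
#' Runs the cross-validated shift-and-sum correlation and the noise ceiling
#' for every prediction condition on one set of per-run trials.
#'
#' @inheritParams crossval_correlation
#' @param conditions data.frame from [default_conditions()].
#' @return data.frame with one row per condition: `condition`, `source`,
#'   `target`, `median_r`, `ceiling_r`, `n_splits`; attribute `splits_r`
#'   holds the per-split correlation matrix (split x condition).
#' @export
additivity_test <- function(trials_by_run, conditions = default_conditions(),
                            splits = NULL,
                            dt = attr(trials_by_run[[1]], "dt") %||% 1.3) {
  n_runs <- length(trials_by_run)
  splits <- splits %||% enumerate_splits(n_runs, n_runs %/% 2)
  res <- lapply(seq_len(nrow(conditions)), function(i) {
    cond <- list(source = conditions$source[i], target = conditions$target[i])
    cv <- crossval_correlation(trials_by_run, cond, splits, dt)
    nc <- noise_ceiling(trials_by_run, conditions$target[i], splits)
    list(row = data.frame(condition = conditions$label[i],
                          source = cond$source, target = cond$target,
                          median_r = cv$median_r, ceiling_r = nc$median_r,
                          n_splits = cv$n_splits),
         r = cv$r)
  })
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  attr(out, "splits_r") <- do.call(cbind, lapply(res, `[[`, "r"))
  colnames(attr(out, "splits_r")) <- conditions$label
  out
}
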