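#' Cut a time course into stimulus-locked trial windows
#'
#' Extracts one window per design block from a single run's time course,
#' starting at the (possibly jittered) stimulus onset and spanning the
#' stimulus duration plus a post-stimulus baseline. Trials are grouped by
#' stimulus duration.
#'
#' @param x Numeric time course for one run, sampled at `dt` starting at 0.
#' @param design A `stimulus_design`.
#' @param run Run index to epoch.
#' @param dt Sampling step of `x` in seconds. Default 1.3.
#' @param baseline Post-stimulus window in seconds. Default 15.6.
#' @return A `trial_set`: named list (one element per duration, names like
#'   `"2.6"`) of trial x time-sample matrices; attributes `durations`, `dt`,
#'   `baseline`.
#' @examples
#' d <- make_design(seed = 1)
#' tc <- rnorm(round(d$run_length / 1.3))
#' tr <- extract_blocks(tc, d, run = 1)
#' vapply(tr, nrow, integer(1))  # 4 trials per duration
#' @export
extract_blocks <- function(x, design, run, dt = 1.3, baseline = 15.6) {
  stopifnot(inherits(design, "stimulus_design"), dt > 0, baseline >= 0)
  b <- design$blocks[design$blocks$run == run, , drop = FALSE]
  durations <- sort(unique(b$duration))
  out <- stats::setNames(vector("list", length(durations)), dur_key(durations))
  for (d in durations) {
    bd <- b[b$duration == d, , drop = FALSE]
    i0 <- grid_steps(bd$onset, dt, "stimulus onset")
    len <- grid_steps(d + baseline, dt, "trial window")
    trials <- matrix(NA_real_, nrow = nrow(bd), ncol = len)
    for (k in seq_len(nrow(bd))) {
      idx <- i0[k] + seq_len(len)
      if (any(idx > length(x))) {
        stop(sprintf("trial window for block at %.1f s (duration %.1f s) in run %d exceeds the run end",
                     bd$onset[k], d, run), call. = FALSE)
      }
      trials[k, ] <- x[idx]
    }
    out[[dur_key(d)]] <- trials
  }
  structure(out, durations = durations, dt = dt, baseline = baseline,
            class = "trial_set")
}

#' Average trials by stimulus duration, with confidence intervals
#'
#' Computes the samplewise mean across trials of each duration and a 95%
#' Student-t confidence interval of the across-trial variability
#' (`t(0.975, n-1) * sd / sqrt(n)` per sample). With a single trial the mean
#' is returned and the CI is marked unavailable (`NA`).
#'
#' @param trials A `trial_set` from [extract_blocks()], or a plain named list
#'   of trial matrices.
#' @param dt Sampling step in seconds (taken from the trial set when present).
#' @param conf Confidence level. Default 0.95.
#' @return An `epoch_set`: named list per duration with `time_s`, `mean`,
#'   `ci_half`, `n`.
#' @export
average_blocks <- function(trials, dt = attr(trials, "dt") %||% 1.3,
                           conf = 0.95) {
  out <- lapply(trials, function(m) {
    m <- rbind(m)  # tolerate a single trial given as a vector
    n <- nrow(m)
    mu <- colMeans(m)
    ci <- if (n >= 2) {
      se <- apply(m, 2, stats::sd) / sqrt(n)
      stats::qt(1 - (1 - conf) / 2, df = n - 1) * se
    } else {
      rep(NA_real_, ncol(m))
    }
    list(time_s = (seq_len(ncol(m)) - 1) * dt, mean = mu, ci_half = ci, n = n)
  })
  structure(out, class = "epoch_set")
}

# Pool trial sets from several runs: per duration, rbind all trial matrices.
pool_trials <- function(trial_sets) {
  durs <- names(trial_sets[[1]])
  out <- stats::setNames(lapply(durs, function(d) {
    do.call(rbind, lapply(trial_sets, `[[`, d))
  }), durs)
  attributes(out)[c("durations", "dt", "baseline")] <-
    attributes(trial_sets[[1]])[c("durations", "dt", "baseline")]
  class(out) <- "trial_set"
  out
}

#' Export an epoch set as a tidy table
#'
#' @param epochs An `epoch_set` from [average_blocks()].
#' @param roi,bin Labels recorded in the table.
#' @return data.frame with columns `roi`, `bin`, `duration`, `time_s`,
#'   `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
epochs_to_table <- function(epochs, roi = NA, bin = NA) {
  do.call(rbind, lapply(names(epochs), function(d) {
    e <- epochs[[d]]
    data.frame(roi = roi, bin = bin, duration = as.numeric(d),
               time_s = e$time_s, mean = e$mean,
               ci_lo = e$mean - e$ci_half, ci_hi = e$mean + e$ci_half,
               n = e$n)
  }))
}
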