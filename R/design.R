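#' Build a counterbalanced block-design stimulus schedule
#'
#' Generates a multi-run block design: per run, `reps_per_duration` blocks of
#' each stimulus duration in seeded counterbalanced (randomly permuted) order,
#' separated by rest periods. Each run starts with one rest block, and half of
#' the stimulus blocks (rounded down), chosen pseudo-randomly per run, have
#' their onset shifted by `+jitter` seconds.
#'
#' Rest periods are laid out on the `dt` grid: the rest budget left after the
#' stimulation time and a reserved post-stimulus window (`rest_mean + jitter`
#' after the final block, so the final epoch window always fits) is split into
#' near-equal gaps before each block, with the remainder spread pseudo-randomly.
#' At the defaults this gives rests of 14.3--15.6 s around the nominal 15.6 s.
#'
#' @param n_runs Number of runs. Default 8.
#' @param durations Stimulus durations in seconds. Default `c(2.6, 5.2, 10.4)`.
#' @param reps_per_duration Blocks of each duration per run. Default 4.
#' @param run_length Run duration in seconds. Default `102 * 2.6`.
#' @param rest_mean Nominal rest-block duration in seconds; also the reserved
#'   post-stimulus window after the last block. Default 15.6.
#' @param jitter Onset jitter in seconds applied to half the blocks. Default
#'   1.3.
#' @param dt Grid step in seconds for onsets and rests. Default 1.3.
#' @param end_pad Extra margin in seconds reserved at the end of the run so
#'   the final epoch window fits on the acquired sample grid (the last volume
#'   of a TR-sampled run lies at `run_length - TR`, not `run_length`).
#'   Default 1.3.
#' @param seed Integer seed controlling block order, jitter assignment, and
#'   rest layout.
#' @return A `stimulus_design` object: list with `blocks` (data.frame of
#'   `run`, `onset`, `duration`), `n_runs`, `run_length`, `dt`.
#' @examples
#' d <- make_design(seed = 1)
#' table(d$blocks$duration) / d$n_runs  # 4 blocks of each duration per run
#' @export
make_design <- function(n_runs = 8,
                        durations = c(2.6, 5.2, 10.4),
                        reps_per_duration = 4,
                        run_length = 102 * 2.6,
                        rest_mean = 15.6,
                        jitter = 1.3,
                        dt = 1.3,
                        end_pad = 1.3,
                        seed = 1) {
  stopifnot(n_runs >= 1, reps_per_duration >= 1, length(durations) >= 1,
            all(durations > 0), run_length > 0, rest_mean > 0, jitter >= 0,
            dt > 0)
  grid_steps(durations, dt, "stimulus duration")
  if (jitter > 0) grid_steps(jitter, dt, "jitter")
  grid_steps(rest_mean, dt, "rest duration")

  n_blocks <- length(durations) * reps_per_duration
  stim_total <- sum(durations) * reps_per_duration
  reserve <- rest_mean + jitter + end_pad
  budget <- run_length - stim_total - reserve
  budget_steps <- floor(budget / dt + 1e-9)

  blocks <- with_seed(seed, {
    out <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      if (budget_steps < n_blocks) {
        stop(sprintf(
          "design does not fit in run %d: %d blocks (%.1f s stimulation + %.1f s reserved baseline) leave %.1f s for %d rest periods",
          r, n_blocks, stim_total, reserve, budget, n_blocks), call. = FALSE)
      }
      dur <- rep(durations, reps_per_duration)
      dur <- dur[sample.int(length(dur))]
      gaps <- rep(budget_steps %/% n_blocks, n_blocks)
      extra <- budget_steps %% n_blocks
      if (extra > 0) {
        idx <- sample.int(n_blocks, extra)
        gaps[idx] <- gaps[idx] + 1L
      }
      onset <- cumsum(gaps) * dt + cumsum(c(0, dur[-n_blocks]))
      # the jitter assignment is drawn even at jitter = 0, so designs that
      # differ only in jitter share block orders and rest layouts per seed
      n_jit <- n_blocks %/% 2
      if (n_jit > 0) {
        jid <- sample.int(n_blocks, n_jit)
        onset[jid] <- onset[jid] + jitter
      }
      out[[r]] <- data.frame(run = r, onset = onset, duration = dur)
    }
    do.call(rbind, out)
  })
  rownames(blocks) <- NULL

  design <- structure(
    list(blocks = blocks, n_runs = n_runs, run_length = run_length, dt = dt),
    class = "stimulus_design")
  validate_design(design, baseline = rest_mean)
  design
}

# Check stimulus_design invariants; `baseline` is the post-stimulus window that
# must fit inside the run for every block.
validate_design <- function(design, baseline = 15.6) {
  b <- design$blocks
  for (r in unique(b$run)) {
    br <- b[b$run == r, ]
    if (is.unsorted(br$onset, strictly = TRUE)) {
      stop(sprintf("onsets not strictly increasing in run %d", r), call. = FALSE)
    }
    over <- br$onset + br$duration + baseline > design$run_length + 1e-9
    if (any(over)) {
      stop(sprintf(
        "block at %.1f s (duration %.1f s) in run %d does not fit inside the run including its %.1f s post-stimulus window",
        br$onset[which(over)[1]], br$duration[which(over)[1]], r, baseline),
        call. = FALSE)
    }
  }
  counts <- table(b$run, b$duration)
  if (length(unique(as.vector(counts))) > 1) {
    stop("unequal counts of stimulus durations across runs", call. = FALSE)
  }
  invisible(design)
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat(sprintf("Stimulus design: %d runs of %.1f s, %d blocks/run (durations: %s s)\n",
              x$n_runs, x$run_length, nrow(x$blocks) / x$n_runs,
              paste(sort(unique(x$blocks$duration)), collapse = ", ")))
  invisible(x)
}

#' Write or read a stimulus design as tab-separated text
#'
#' The on-disk format has columns `run`, `onset_s`, `duration_s`.
#'
#' @param design A `stimulus_design`.
#' @param path File path.
#' @param run_length,dt,n_runs Metadata needed to rebuild the design on read;
#'   `read_design` takes them as arguments because the TSV stores only blocks.
#' @return `read_design` returns a `stimulus_design`.
#' @export
write_design <- function(design, path) {
  b <- design$blocks
  utils::write.table(
    data.frame(run = b$run, onset_s = b$onset, duration_s = b$duration),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, run_length, dt = 1.3, n_runs = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("run", "onset_s", "duration_s")
  if (!all(need %in% names(tab))) {
    stop("design file must have columns run, onset_s, duration_s", call. = FALSE)
  }
  structure(
    list(blocks = data.frame(run = tab$run, onset = tab$onset_s,
                             duration = tab$duration_s),
         n_runs = n_runs %||% max(tab$run),
         run_length = run_length, dt = dt),
    class = "stimulus_design")
}
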