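#' Aggregate per-subject additivity results at the group level
#'
#' Stacks per-subject result tables into one long table and computes the
#' group mean with a Student-t 95% confidence interval per (ROI, depth bin,
#' condition). Subjects must share the same bin structure and conditions.
#'
#' @param results Named list of per-subject data.frames with columns `roi`,
#'   `bin`, `mean_depth`, `condition`, `median_r` (one name per subject), as
#'   produced by [analyze_study()].
#' @param conf Confidence level. Default 0.95.
#' @return List with `long` (subject-level table) and `summary` (group mean,
#'   `ci_half`, `n_subjects` per ROI/bin/condition; `ci_half` is `NA` for a
#'   single subject).
#' @export
aggregate_group <- function(results, conf = 0.95) {
  stopifnot(length(results) >= 1)
  if (is.null(names(results))) names(results) <- paste0("S", seq_along(results))
  key <- function(d) paste(d$roi, d$bin, d$condition, sep = "|")
  ref <- sort(key(results[[1]]))
  for (s in seq_along(results)) {
    if (!identical(sort(key(results[[s]])), ref)) {
      stop(sprintf("subject '%s' has inconsistent bins/conditions",
                   names(results)[s]), call. = FALSE)
    }
  }
  long <- do.call(rbind, lapply(names(results), function(s) {
    d <- results[[s]]
    data.frame(subject = s, roi = d$roi, bin = d$bin,
               mean_depth = d$mean_depth, condition = d$condition,
               r = d$median_r)
  }))
  agg <- split(long, key(long))
  summary <- do.call(rbind, lapply(agg, function(g) {
    n <- nrow(g)
    ci <- if (n >= 2) {
      stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(g$r) / sqrt(n)
    } else {
      NA_real_
    }
    data.frame(roi = g$roi[1], bin = g$bin[1],
               mean_depth = mean(g$mean_depth), condition = g$condition[1],
               mean_r = mean(g$r), ci_half = ci, n_subjects = n)
  }))
  rownames(summary) <- NULL
  list(long = long, summary = summary[order(summary$roi, summary$bin), ])
}

#' Linear fit of prediction correlations across cortical depth
#'
#' Ordinary least squares of correlation on mean normalized depth,
#' `r = intercept + slope * depth`, with two-sided t-tests of `slope = 0`
#' and `intercept = 0` at `df = n - 2`. When the residual standard deviation
#' falls below 1e-6 — correlations are order-1 quantities, so smaller
#' residuals are numerical noise — the fit is treated as numerically exact:
#' each p-value is 1 when the corresponding coefficient is below 1e-6 in
#' magnitude and 0 otherwise, and the t statistic is reported as 0 or
#' (signed) infinity.
#'
#' @param points data.frame with columns `depth` (normalized, per-bin mean)
#'   and `r` (prediction correlation), typically one row per
#'   subject x condition x bin.
#' @param roi Optional ROI label stored in the fit.
#' @return A `trend_fit`: list with `roi`, `slope`, `intercept`, `t_slope`,
#'   `t_intercept`, `p_slope`, `p_intercept`, `df`, `n_points`.
#' @export
fit_depth_trend <- function(points, roi = NA) {
  stopifnot(all(c("depth", "r") %in% names(points)))
  n <- nrow(points)
  if (n < 3) stop("depth-trend fit needs at least 3 points", call. = FALSE)
  if (stats::sd(points$depth) == 0) {
    stop("degenerate depth-trend design: all depth values equal", call. = FALSE)
  }
  fit <- stats::lm(r ~ depth, data = points)
  df <- n - 2L
  rss <- sum(stats::residuals(fit)^2)
  s <- sqrt(rss / df)
  coefs <- stats::coef(fit)
  intercept <- unname(coefs[1])
  slope <- unname(coefs[2])
  if (s < 1e-6) {
    stat <- function(b) if (abs(b) < 1e-6) 0 else sign(b) * Inf
    pval <- function(b) if (abs(b) < 1e-6) 1 else 0
    t_slope <- stat(slope); p_slope <- pval(slope)
    t_intercept <- stat(intercept); p_intercept <- pval(intercept)
  } else {
    sm <- summary(fit)$coefficients
    t_intercept <- sm[1, "t value"]; p_intercept <- sm[1, "Pr(>|t|)"]
    t_slope <- sm[2, "t value"]; p_slope <- sm[2, "Pr(>|t|)"]
  }
  structure(list(roi = roi, slope = slope, intercept = intercept,
                 t_slope = t_slope, t_intercept = t_intercept,
                 p_slope = p_slope, p_intercept = p_intercept,
                 df = df, n_points = n),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(format_trend(x), sep = "\n")
  invisible(x)
}

# Journal-style reporting lines for a trend fit.
format_trend <- function(fit) {
  c(sprintf("ROI %s: intercept = %.2f, t(%d) = %.2f, p = %.3g",
            fit$roi, fit$intercept, fit$df, fit$t_intercept, fit$p_intercept),
    sprintf("ROI %s: slope = %.2f, t(%d) = %.2f, p = %.3g",
            fit$roi, fit$slope, fit$df, fit$t_slope, fit$p_slope))
}

#' Horizontality verdict for a depth trend
#'
#' Temporal additivity across cortical depth predicts a flat (horizontal)
#' profile of prediction correlations over depth. The verdict uses only the
#' slope test: `consistent-with-additivity` when `p_slope >= alpha`,
#' `violated` otherwise. The intercept test (is the overall correlation
#' nonzero?) never enters the verdict.
#'
#' @param fit A `trend_fit`.
#' @param alpha Significance level. Default 0.05.
#' @return `"consistent-with-additivity"` or `"violated"`.
#' @examples
#' f <- fit_depth_trend(data.frame(depth = c(.1, .5, .9), r = c(.9, .91, .9)))
#' test_horizontal(f)
#' @export
test_horizontal <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "trend_fit"), alpha > 0, alpha <= 1)
  if (fit$p_slope >= alpha) "consistent-with-additivity" else "violated"
}
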