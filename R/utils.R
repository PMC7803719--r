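# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG flow.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# TRUE when x is a multiple of step on a tolerant grid.
on_grid <- function(x, step, tol = 1e-6) {
  abs(x / step - round(x / step)) < tol
}

# Integer number of grid steps in x, erroring when x is off-grid.
grid_steps <- function(x, step, what = "value") {
  if (!all(on_grid(x, step))) {
    stop(sprintf("%s not on the %.9g s sampling grid: %s",
                 what, step, paste(format(x[!on_grid(x, step)]), collapse = ", ")),
         call. = FALSE)
  }
  as.integer(round(x / step))
}

# Row-wise Pearson correlation of two matrices with matching dimensions.
# Returns NA for rows where either side has zero variance.
row_cor <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  num <- rowSums(ac * bc)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical list name for a stimulus duration (no padding, stable across
# scalar and vector calls).
dur_key <- function(d) sprintf("%.8g", d)
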