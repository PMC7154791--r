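# Internal helpers shared across modules.

# Stage-scoped seed derived from a master seed so that inserting a stage
# does not perturb the random streams of later stages. Kept below 2^31.
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Separable Gaussian blur of a matrix; the workhorse for spatially
# autocorrelated random fields. Kernels are truncated at the matrix edge
# and renormalised, so the filter preserves the mean near borders.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  blur_1d <- function(mat, kern) {
    n <- nrow(mat)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- seq(max(1L, i - half), min(n, i + half))
      w <- kern[j - i + half + 1L]
      K[i, j] <- w / sum(w)
    }
    K %*% mat
  }
  t(blur_1d(t(blur_1d(m, k)), k))
}

# Smoothed standard-normal random field on an n_rows x n_cols grid,
# rescaled back to unit marginal variance after blurring.
smooth_field <- function(n_rows, n_cols, sigma) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  s <- gaussian_blur(z, sigma)
  s / stats::sd(as.vector(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
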