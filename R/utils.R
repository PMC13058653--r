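# Internal helpers shared across modules.

# z-score with population SD (ddof = 0); errors on zero variance.
zscore_pop <- function(x, what = "values") {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0) {
    abort(sprintf("cannot z-score %s: zero variance", what),
          class = "mindgrad_degenerate_input")
  }
  (x - m) / s
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)),
          class = "mindgrad_invalid_argument")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, lower),
          class = "mindgrad_invalid_argument")
  }
  invisible(as.integer(x))
}

# Squared-exponential Gaussian-process draw over points on the unit sphere,
# using chordal (Euclidean) distances. Returns one draw per column of `n_draws`.
gp_sphere_draw <- function(centroids, lengthscale, n_draws = 1L, nugget = 1e-8) {
  d2 <- as.matrix(stats::dist(centroids))^2
  K <- exp(-d2 / (2 * lengthscale^2))
  diag(K) <- diag(K) + nugget
  L <- chol(K)
  z <- matrix(rnorm(nrow(K) * n_draws), nrow(K), n_draws)
  crossprod(L, z)
}

# Pearson correlations between each column of X and vector y, vectorised.
col_cor <- function(X, y) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  num <- crossprod(Xc, yc)
  den <- sqrt(colSums(Xc^2) * sum(yc^2))
  as.numeric(num) / as.numeric(den)
}
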