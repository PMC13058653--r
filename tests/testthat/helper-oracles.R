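# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms from the code under test.

# Closed-form KL divergence between multivariate Gaussians N(mu1, S1) and
# N(mu2, S2).
gaussian_kl <- function(mu1, S1, mu2, S2) {
  d <- length(mu1)
  S2inv <- solve(S2)
  0.5 * (sum(diag(S2inv %*% S1)) +
           t(mu2 - mu1) %*% S2inv %*% (mu2 - mu1) - d +
           log(det(S2) / det(S1)))[1, 1]
}

# Region-wise GLM group t-values by explicit normal equations (pseudoinverse),
# independent of the QR path in fit_region_glm.
glm_t_oracle <- function(Y, covariates) {
  grp <- as.integer(as.character(covariates$group) == "case")
  age_c <- covariates$age - mean(covariates$age)
  edu_c <- covariates$education - mean(covariates$education)
  sex <- as.numeric(covariates$sex)
  X <- cbind(1, grp, age_c, sex, edu_c, age_c * sex)
  XtX_inv <- solve(t(X) %*% X)
  H <- XtX_inv %*% t(X)
  df <- nrow(X) - ncol(X)
  apply(as.matrix(Y), 2, function(y) {
    b <- H %*% y
    res <- y - X %*% b
    se <- sqrt(sum(res^2) / df * XtX_inv[2, 2])
    b[2] / se
  })
}

# Hand step-up BH q-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# First-component NIPALS PLS fit of centered y on z-scored X; returns the
# one-component fitted response.
nipals_fitted1 <- function(X, y) {
  Xs <- apply(X, 2, function(c) (c - mean(c)) / sqrt(mean((c - mean(c))^2)))
  yc <- y - mean(y)
  w <- crossprod(Xs, yc)
  w <- w / sqrt(sum(w^2))
  t1 <- Xs %*% w
  q1 <- sum(t1 * yc) / sum(t1^2)
  as.numeric(t1 * q1)
}

# LMG shares by brute-force enumeration of all p! orderings.
lmg_factorial_oracle <- function(X, y) {
  p <- ncol(X)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    f <- lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  perms <- matrix(unlist(combinat_perms(seq_len(p))), ncol = p, byrow = TRUE)
  shares <- numeric(p)
  for (i in seq_len(nrow(perms))) {
    ord <- perms[i, ]
    prev <- 0
    for (j in seq_len(p)) {
      cur <- r2(ord[seq_len(j)])
      shares[ord[j]] <- shares[ord[j]] + (cur - prev)
      prev <- cur
    }
  }
  shares / nrow(perms)
}

# All permutations of a small vector (recursive; fine for p <= 5).
combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Max ECDF gap (two-sample KS statistic) by brute force.
ks_stat_oracle <- function(a, b) {
  grid <- sort(c(a, b))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

# Small parcellation + ensemble fixtures shared across tests.
small_parcellation <- function(n = 16L, seed = 42L) {
  generate_parcellation(n, seed = seed)
}
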