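# PLS decoding of a contrast map against term maps or gene expression:
# SIMPLS regression, spin significance of the first component's variance
# explained, and bootstrap weight Z-scores with BH-FDR retention.

# SIMPLS for a univariate response. X must be column-centered (we z-score),
# y centered. Returns weights in the original predictor basis, orthonormal
# scores, per-component y loadings q (scores' covariance with y), and the
# incremental fraction of Var(y) explained by components 1..i.
simpls_fit <- function(X, y, n_components) {
  n <- nrow(X); P <- ncol(X)
  A <- n_components
  W <- matrix(0, P, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  V <- matrix(0, P, A)
  s <- crossprod(X, y)
  for (a in seq_len(A)) {
    r <- s
    t_a <- X %*% r
    tnorm <- sqrt(sum(t_a^2))
    if (tnorm < 1e-300) {
      # response variance exhausted; keep zero components
      break
    }
    t_a <- t_a / tnorm
    r <- r / tnorm
    p_a <- crossprod(X, t_a)
    v <- p_a
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_a)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    W[, a] <- r
    Tm[, a] <- t_a
    q[a] <- sum(t_a * y)
    V[, a] <- v
  }
  list(weights = W, scores = Tm, q = q,
       variance_explained_y = q^2 / sum(y^2))
}

#' Fit a PLS regression of a region map on a predictor matrix
#'
#' SIMPLS partial least squares with a univariate response: components are
#' linear combinations of the (z-scored) predictor columns maximizing
#' covariance with the (centered) response. Every component is oriented so
#' its region scores correlate nonnegatively with the response; in
#' particular the PLS1 score map correlates positively with the target.
#'
#' @param X Regions x predictors numeric matrix (predictor ids as column
#'   names); columns are z-scored internally (population SD).
#' @param y Response map over the same regions (numeric vector or
#'   `contrast_result`, whose `t` column is used).
#' @param n_components Number of components to extract (default 20).
#' @return A `pls_result`: `weights` (P x k, predictor basis),
#'   `region_scores` (R x k, orthonormal), `variance_explained_y` (fraction
#'   of Var(y) captured by each successive component), `n_components`.
#' @export
fit_pls <- function(X, y, n_components = 20L) {
  if (inherits(y, "contrast_result")) y <- y$t
  X <- as.matrix(X)
  n_components <- check_count(n_components, "n_components")
  if (nrow(X) != length(y)) {
    abort("X rows and y length must match", class = "mindgrad_dimension_error")
  }
  if (nrow(X) <= n_components) {
    abort("need more regions than components",
          class = "mindgrad_invalid_argument")
  }
  if (pop_sd(y) == 0) {
    abort("constant response map", class = "mindgrad_degenerate_response")
  }
  Xs <- apply(X, 2, zscore_pop, what = "predictor column")
  yc <- y - mean(y)
  fit <- simpls_fit(Xs, yc, n_components)
  flip <- fit$q < 0
  fit$weights[, flip] <- -fit$weights[, flip]
  fit$scores[, flip] <- -fit$scores[, flip]
  fit$q[flip] <- -fit$q[flip]
  pred_ids <- colnames(X)
  if (is.null(pred_ids)) pred_ids <- paste0("x", seq_len(ncol(X)))
  rownames(fit$weights) <- pred_ids
  colnames(fit$weights) <- paste0("pls", seq_len(n_components))
  rownames(fit$scores) <- rownames(X)
  colnames(fit$scores) <- colnames(fit$weights)
  structure(
    list(n_components = n_components, weights = fit$weights,
         region_scores = fit$scores,
         variance_explained_y = fit$variance_explained_y,
         p_spin_component1 = NA_real_),
    class = "pls_result"
  )
}

#' Spin significance of the first PLS component
#'
#' Recomputes the variance explained by the first component with the
#' response spin-permuted per ensemble entry; one-sided
#' `p = (1 + #\{null >= observed\}) / (1 + n_spins)` since larger explained
#' variance means more structure.
#'
#' @inheritParams fit_pls
#' @param ensemble `spin_ensemble` over the response's regions.
#' @return Tibble with `variance_explained` (observed, component 1) and
#'   `p_spin`.
#' @export
spin_significance_of_component <- function(X, y, ensemble,
                                           n_components = 20L) {
  if (inherits(y, "contrast_result")) y <- y$t
  y <- region_values(y, ensemble$region_id, "response map")
  X <- as.matrix(X)
  Xs <- apply(X, 2, zscore_pop, what = "predictor column")
  obs <- simpls_fit(Xs, y - mean(y), 1L)$variance_explained_y[1]
  perms <- ensemble$permutations
  null <- vapply(seq_len(ensemble$n_spins), function(s) {
    ys <- y[perms[s, ]]
    simpls_fit(Xs, ys - mean(ys), 1L)$variance_explained_y[1]
  }, numeric(1))
  tibble::tibble(
    variance_explained = obs,
    p_spin = (1 + sum(null >= obs)) / (1 + ensemble$n_spins)
  )
}

#' Bootstrap Z-scores for PLS1 predictor weights
#'
#' Resamples regions with replacement, refits the PLS, sign-aligns each
#' bootstrap first component to the original (flipped when the weight
#' correlation is negative), and normalizes each original weight by its
#' bootstrap SD. Two-sided normal p-values are BH-FDR corrected and the
#' significant predictors split by weight sign into positive and negative
#' sets.
#'
#' @inheritParams fit_pls
#' @param n_boot Number of bootstrap resamples (>= 100; the reference
#'   analyses use 10,000).
#' @param seed Integer seed for the resampling.
#' @param fdr_level FDR level for retention.
#' @return Tibble with one row per predictor: `predictor`, `weight`
#'   (original PLS1 weight), `z`, `p`, `q`, `significant`, `direction`
#'   ("positive"/"negative").
#' @export
bootstrap_weight_z <- function(X, y, n_components = 20L, n_boot = 1000L,
                               seed = 1L, fdr_level = 0.05) {
  n_boot <- check_count(n_boot, "n_boot", lower = 100L)
  if (inherits(y, "contrast_result")) y <- y$t
  X <- as.matrix(X)
  orig <- fit_pls(X, y, n_components)
  w1 <- orig$weights[, 1]
  R <- nrow(X)

  boot_w <- eval_with_seed(seed, {
    out <- matrix(NA_real_, length(w1), n_boot)
    for (b in seq_len(n_boot)) {
      wb <- NULL
      for (try in 1:25) {
        idx <- sample.int(R, R, replace = TRUE)
        if (length(unique(idx)) <= n_components) next
        wb <- tryCatch(
          fit_pls(X[idx, , drop = FALSE], y[idx], n_components)$weights[, 1],
          mindgrad_degenerate_input = function(e) NULL,
          mindgrad_degenerate_response = function(e) NULL
        )
        if (!is.null(wb)) break
      }
      if (is.null(wb)) {
        abort("bootstrap resampling failed repeatedly (degenerate resamples)",
              class = "mindgrad_bootstrap_error")
      }
      if (cor(wb, w1) < 0) wb <- -wb
      out[, b] <- wb
    }
    out
  })

  sd_boot <- apply(boot_w, 1, sd)
  z <- w1 / sd_boot
  p <- 2 * pnorm(-abs(z))
  q <- bh_fdr(p)
  tibble::tibble(
    predictor = names(w1), weight = unname(w1), z = unname(z),
    p = p, q = q, significant = q < fdr_level,
    direction = ifelse(w1 > 0, "positive", "negative")
  )
}

#' Spin correlation of the PLS1 score map with a target map
#'
#' @param result A `pls_result`.
#' @param y Target map over the same regions.
#' @param ensemble A `spin_ensemble`.
#' @export
score_target_correlation <- function(result, y, ensemble) {
  if (inherits(y, "contrast_result")) y <- y$t
  spin_correlation_test(result$region_scores[, 1], y, ensemble)
}

#' Full PLS decoding of a contrast map
#'
#' Convenience wrapper running [fit_pls()], [spin_significance_of_component()]
#' and [bootstrap_weight_z()] and attaching the results to the fitted object.
#'
#' @inheritParams bootstrap_weight_z
#' @param ensemble `spin_ensemble` for the component-significance test.
#' @return A `pls_result` with `p_spin_component1` filled and a
#'   `predictors` tibble (output of [bootstrap_weight_z()]) attached.
#' @export
decode_pls <- function(X, y, ensemble, n_components = 20L, n_boot = 1000L,
                       seed = 1L, fdr_level = 0.05) {
  fit <- fit_pls(X, y, n_components)
  fit$p_spin_component1 <-
    spin_significance_of_component(X, y, ensemble, n_components)$p_spin
  fit$predictors <- bootstrap_weight_z(X, y, n_components, n_boot, seed,
                                       fdr_level)
  fit
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %d predictors, %d components\n",
              nrow(x$weights), x$n_components))
  cat(sprintf("  PLS1 variance explained: %.1f%%%s\n",
              100 * x$variance_explained_y[1],
              if (!is.na(x$p_spin_component1))
                sprintf(" (p_spin = %.4g)", x$p_spin_component1) else ""))
  invisible(x)
}

#' Tidy PLS predictor weights
#' @param x A `pls_result`.
#' @param ... Unused.
#' @export
tidy.pls_result <- function(x, ...) {
  if (!is.null(x$predictors)) return(x$predictors)
  tibble::tibble(predictor = rownames(x$weights),
                 weight = unname(x$weights[, 1]))
}

#' One-row PLS summary
#' @param x A `pls_result`.
#' @param ... Unused.
#' @export
glance.pls_result <- function(x, ...) {
  tibble::tibble(
    n_predictors = nrow(x$weights), n_components = x$n_components,
    var_explained_pls1 = x$variance_explained_y[1],
    p_spin_component1 = x$p_spin_component1,
    n_significant = if (!is.null(x$predictors)) sum(x$predictors$significant)
                    else NA_integer_
  )
}

#' Variance-explained profile of a PLS fit
#' @param object A `pls_result`.
#' @param ... Unused.
#' @export
autoplot.pls_result <- function(object, ...) {
  df <- tibble::tibble(component = seq_along(object$variance_explained_y),
                       variance_explained = object$variance_explained_y)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$variance_explained)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$component, yend = 0)) +
    ggplot2::geom_point(colour = "firebrick", size = 2) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "PLS component", y = "Variance of response explained")
}
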