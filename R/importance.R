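# Multiple linear regression of the contrast map on molecular/genetic
# predictor maps, with exact LMG relative-importance decomposition (average
# R-squared increment over all predictor orderings, computed by subset
# enumeration) and bootstrap confidence intervals on the percentage shares.

# R-squared of y on the columns of X indexed by `subset` (with intercept).
subset_r2 <- function(X, y, subset) {
  if (!length(subset)) return(0)
  fit <- stats::lm.fit(cbind(1, X[, subset, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

# Exact LMG shares via enumeration of all 2^p subsets. Share of predictor j
# is the weighted average of R2(S + j) - R2(S) over subsets S not containing
# j, with weight |S|! (p - |S| - 1)! / p!.
lmg_shares <- function(X, y) {
  p <- ncol(X)
  subsets <- 0:(2^p - 1)
  r2 <- vapply(subsets, function(mask) {
    subset_r2(X, y, which(bitwAnd(mask, bitwShiftL(1, 0:(p - 1))) > 0))
  }, numeric(1))
  lw <- lgamma(0:p + 1)  # log factorials
  shares <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1, j - 1)
    without <- subsets[bitwAnd(subsets, bit) == 0]
    sizes <- vapply(without, function(m) sum(bitwAnd(m, bitwShiftL(1, 0:(p - 1))) > 0),
                    numeric(1))
    w <- exp(lw[sizes + 1] + lw[p - sizes] - lw[p + 1])
    shares[j] <- sum(w * (r2[match(without + bit, subsets)] - r2[match(without, subsets)]))
  }
  shares
}

#' Relative-importance regression of a contrast map on predictor maps
#'
#' Fits ordinary least squares of the t-map on up to 10 predictor maps,
#' decomposes the model R-squared into exact LMG shares (averaging the
#' sequential R-squared increment of each predictor over all orderings),
#' assesses fit significance by spin-permuting the response and recomputing
#' R-squared, and bootstraps regions for percentile confidence intervals on
#' the percentage shares.
#'
#' @param y Response map (numeric vector or `contrast_result`).
#' @param predictors Regions x p numeric matrix with named columns (p <= 10;
#'   exact LMG enumerates all subsets).
#' @param ensemble Optional `spin_ensemble` for the fit-significance test.
#' @param n_boot Bootstrap iterations for share CIs (reference analyses use
#'   1,000); 0 skips the bootstrap.
#' @param seed Integer seed.
#' @return An `importance_result`: list with `shares` tibble (`predictor`,
#'   `coefficient`, `lmg`, `share_pct`, `ci_lower`, `ci_upper`), `r2`,
#'   `adjusted_r2`, `p_spin_fit`.
#' @export
fit_importance <- function(y, predictors, ensemble = NULL, n_boot = 1000L,
                           seed = 1L) {
  if (inherits(y, "contrast_result")) y <- y$t
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  if (p > 10L) {
    abort("exact LMG enumerates 2^p subsets; use at most 10 predictors",
          class = "mindgrad_complexity_error")
  }
  if (nrow(X) != length(y)) {
    abort("predictors and response differ in length",
          class = "mindgrad_dimension_error")
  }
  if (qr(cbind(1, X))$rank < p + 1L) {
    abort("predictors are collinear to machine precision",
          class = "mindgrad_collinearity_error")
  }
  n <- length(y)
  full <- stats::lm.fit(cbind(intercept = 1, X), y)
  r2 <- 1 - sum(full$residuals^2) / sum((y - mean(y))^2)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  shares <- lmg_shares(X, y)
  share_pct <- 100 * shares / sum(shares)

  p_spin <- NA_real_
  if (!is.null(ensemble)) {
    yv <- region_values(y, ensemble$region_id, "response map")
    null_r2 <- vapply(seq_len(ensemble$n_spins), function(s) {
      subset_r2(X, yv[ensemble$permutations[s, ]], seq_len(p))
    }, numeric(1))
    p_spin <- (1 + sum(null_r2 >= r2)) / (1 + ensemble$n_spins)
  }

  ci <- matrix(NA_real_, p, 2)
  if (n_boot > 0) {
    boot_pct <- eval_with_seed(seed, {
      out <- matrix(NA_real_, n_boot, p)
      for (b in seq_len(n_boot)) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          Xb <- X[idx, , drop = FALSE]
          if (qr(cbind(1, Xb))$rank == p + 1L) break
        }
        sb <- lmg_shares(Xb, y[idx])
        out[b, ] <- 100 * sb / sum(sb)
      }
      out
    })
    ci <- t(apply(boot_pct, 2, quantile, c(0.025, 0.975)))
  }

  structure(
    list(
      shares = tibble::tibble(
        predictor = colnames(X),
        coefficient = unname(full$coefficients[-1]),
        lmg = shares, share_pct = share_pct,
        ci_lower = ci[, 1], ci_upper = ci[, 2]
      ),
      r2 = r2, adjusted_r2 = adj_r2, p_spin_fit = p_spin, n_regions = n
    ),
    class = "importance_result"
  )
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("<importance_result> R2 = %.3f (adjusted %.3f)%s\n",
              x$r2, x$adjusted_r2,
              if (!is.na(x$p_spin_fit))
                sprintf(", p_spin = %.4g", x$p_spin_fit) else ""))
  print(x$shares)
  invisible(x)
}

#' Tidy LMG shares
#' @param x An `importance_result`.
#' @param ... Unused.
#' @export
tidy.importance_result <- function(x, ...) x$shares

#' One-row model summary
#' @param x An `importance_result`.
#' @param ... Unused.
#' @export
glance.importance_result <- function(x, ...) {
  tibble::tibble(r2 = x$r2, adjusted_r2 = x$adjusted_r2,
                 p_spin_fit = x$p_spin_fit, n_regions = x$n_regions,
                 n_predictors = nrow(x$shares))
}

#' Bar chart of relative-importance shares
#' @param object An `importance_result`.
#' @param ... Unused.
#' @export
autoplot.importance_result <- function(object, ...) {
  df <- object$shares
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$predictor,
                                                  .data$share_pct),
                                   .data$share_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative contribution to R2 (%)")
}
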