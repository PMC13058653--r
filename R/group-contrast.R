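# Region-wise case-control contrasts of the principal gradient: covariate
# GLM per region, BH-FDR, network/class aggregation, distribution tests, and
# comparison of the t-map with a reference map under the spin null.

contrast_design <- function(covariates) {
  needed <- c("group", "age", "sex", "education")
  if (!all(needed %in% names(covariates))) {
    abort("covariates must have columns group, age, sex, education",
          class = "mindgrad_invalid_argument")
  }
  grp <- covariates$group
  if (is.character(grp) || is.factor(grp)) {
    grp <- as.integer(as.character(grp) == "case")
  }
  if (length(unique(grp)) < 2L || min(table(grp)) < 2L) {
    abort("need at least 2 subjects in each group",
          class = "mindgrad_design_error")
  }
  # age and education mean-centered so the age x sex interaction leaves the
  # main effects interpretable
  age_c <- covariates$age - mean(covariates$age)
  edu_c <- covariates$education - mean(covariates$education)
  sex <- as.numeric(covariates$sex)
  X <- cbind(intercept = 1, group = grp, age = age_c, sex = sex,
             education = edu_c, age_sex = age_c * sex)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(paste("design matrix is rank deficient; collinear columns:",
                paste(bad, collapse = ", ")),
          class = "mindgrad_design_error")
  }
  X
}

#' Region-wise GLM contrast of principal-gradient scores
#'
#' For every region, fits ordinary least squares of the principal-gradient
#' score on group (control = 0, case = 1, so positive t means case > control),
#' age, sex, education, and the age x sex interaction (age and education
#' mean-centered), and reports the group coefficient's t-statistic, two-sided
#' p-value, BH-FDR q-value, and a q < `fdr_level` significance flag.
#'
#' @param gradient1 Subjects x regions numeric matrix of principal-gradient
#'   scores (region ids as column names).
#' @param covariates Tibble with `group` ("case"/"control" or 0/1), `age`,
#'   `sex` (0/1), `education`, in the same subject order as `gradient1` rows.
#' @param fdr_level FDR significance level (default 0.05).
#' @return A `contrast_result` tibble: `region_id`, `t`, `p`, `q`,
#'   `significant`.
#' @export
fit_region_glm <- function(gradient1, covariates, fdr_level = 0.05) {
  Y <- as.matrix(gradient1)
  if (nrow(Y) != nrow(covariates)) {
    abort("gradient1 rows and covariates rows must match",
          class = "mindgrad_dimension_error")
  }
  X <- contrast_design(covariates)
  qrx <- qr(X)
  df <- nrow(X) - ncol(X)
  if (df < 1L) {
    abort("too few subjects for the covariate model (residual df < 1)",
          class = "mindgrad_insufficient_sample")
  }
  coefs <- qr.coef(qrx, Y)
  res <- Y - X %*% coefs
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrx))
  v_group <- xtx_inv[2, 2]
  tval <- as.numeric(coefs["group", ] / sqrt(sigma2 * v_group))
  pval <- 2 * pt(-abs(tval), df)
  q <- bh_fdr(pval)
  nm <- colnames(Y)
  ids <- if (is.null(nm)) seq_len(ncol(Y)) else {
    ri <- suppressWarnings(as.integer(nm))
    if (anyNA(ri)) nm else ri
  }
  out <- tibble::tibble(
    region_id = ids,
    t = tval, p = pval, q = q,
    significant = q < fdr_level
  )
  class(out) <- c("contrast_result", class(out))
  attr(out, "df") <- df
  attr(out, "covariate_set") <- colnames(X)[-1]
  out
}

#' Benjamini-Hochberg FDR q-values
#'
#' Standard step-up q-values (monotonicity enforced), returned in the input
#' order.
#'
#' @param p_values Numeric p-values in [0, 1].
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "mindgrad_invalid_argument")
  }
  p.adjust(p_values, method = "BH")
}

#' Aggregate gradient scores by atlas label and contrast the aggregates
#'
#' Averages each subject's principal-gradient scores within each network (or
#' cytoarchitectonic class) label, then applies the same covariate GLM to
#' the label means, with BH-FDR across labels.
#'
#' @inheritParams fit_region_glm
#' @param parcellation Parcellation providing the labels.
#' @param atlas Which label set to use: "network" or "class".
#' @return A `contrast_result` tibble with a `label` column.
#' @export
aggregate_by_label <- function(gradient1, covariates, parcellation,
                               atlas = c("network", "class"),
                               fdr_level = 0.05) {
  atlas <- match.arg(atlas)
  labels <- parcellation[[paste0(atlas, "_label")]]
  Y <- as.matrix(gradient1)
  if (ncol(Y) != length(labels)) {
    abort("gradient1 columns and parcellation rows must match",
          class = "mindgrad_dimension_error")
  }
  ulab <- sort(unique(labels))
  if (any(!table(factor(labels, levels = ulab)))) {
    abort("every label must contain at least one region",
          class = "mindgrad_labeling_error")
  }
  means <- vapply(ulab, function(l) {
    rowMeans(Y[, labels == l, drop = FALSE])
  }, numeric(nrow(Y)))
  colnames(means) <- ulab
  fit <- fit_region_glm(means, covariates, fdr_level)
  out <- tibble::tibble(label = ulab, t = fit$t, p = fit$p, q = fit$q,
                        significant = fit$significant)
  class(out) <- c("contrast_result", class(out))
  attr(out, "df") <- attr(fit, "df")
  attr(out, "covariate_set") <- attr(fit, "covariate_set")
  out
}

#' Kolmogorov-Smirnov test on subject-level mean gradient scores
#'
#' Two-sample KS test comparing the distributions of per-subject mean
#' principal-gradient scores between cases and controls.
#'
#' @param mean_g1_cases,mean_g1_controls Numeric vectors of subject-level
#'   means (at least 5 per group).
#' @return Tibble with `statistic` and `p`.
#' @export
distribution_test <- function(mean_g1_cases, mean_g1_controls) {
  if (length(mean_g1_cases) < 5L || length(mean_g1_controls) < 5L) {
    abort("need at least 5 subjects per group",
          class = "mindgrad_insufficient_sample")
  }
  ks <- suppressWarnings(ks.test(mean_g1_cases, mean_g1_controls))
  tibble::tibble(statistic = unname(ks$statistic), p = ks$p.value)
}

#' Spatial correlation of the contrast t-map with a reference map
#'
#' Spin-permutation test of the Pearson correlation between the case-control
#' t-map and a reference map (e.g. the control-group mean gradient); a
#' positive correlation means regions at the extremes of the reference map
#' show the largest group differences.
#'
#' @param t_map Numeric vector or `contrast_result` (its `t` column is used).
#' @param reference_map Numeric vector or tibble over the same regions.
#' @param ensemble A `spin_ensemble`.
#' @export
tmap_vs_reference <- function(t_map, reference_map, ensemble) {
  if (inherits(t_map, "contrast_result")) t_map <- t_map$t
  spin_correlation_test(t_map, reference_map, ensemble)
}

#' One-row contrast summary
#' @param x A `contrast_result`.
#' @param ... Unused.
#' @export
glance.contrast_result <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x), n_significant = sum(x$significant),
    max_abs_t = max(abs(x$t)), min_q = min(x$q)
  )
}

#' t-value map plot for a contrast
#' @param object A `contrast_result` with a `region_id` column.
#' @param parcellation Parcellation supplying centroids.
#' @param ... Unused.
#' @export
autoplot.contrast_result <- function(object, parcellation = NULL, ...) {
  if (is.null(parcellation) || !"region_id" %in% names(object)) {
    df <- tibble::as_tibble(object)
    df$idx <- seq_len(nrow(df))
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$idx, .data$t,
                                       fill = .data$significant)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = NULL, y = "t (case - control)")
    )
  }
  df <- dplyr::left_join(tibble::as_tibble(object),
                         parcellation[, c("region_id", "y", "z", "hemisphere")],
                         by = "region_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$y, .data$z, colour = .data$t)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::scale_colour_gradient2(low = "navy", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, title = "Case-control t-map")
}
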