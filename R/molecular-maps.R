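# Molecular contextualization: spin-tested correlations of the contrast
# t-map with an annotation panel (receptor/transporter maps) and the
# excitatory/inhibitory ratio map.

check_panel <- function(panel) {
  if (!is.list(panel) || !all(c("values", "info") %in% names(panel))) {
    abort("panel must be a list with `values` (matrix) and `info` (tibble)",
          class = "mindgrad_invalid_panel")
  }
  if (ncol(panel$values) != nrow(panel$info)) {
    abort("panel values and info disagree on the number of maps",
          class = "mindgrad_invalid_panel")
  }
  invisible(panel)
}

#' Correlate a t-map with every map of an annotation panel
#'
#' Runs [spin_correlation_test()] of the t-map against each panel map and
#' applies Bonferroni correction across the panel (family size = number of
#' maps), mirroring the multiple-testing treatment of a receptor/transporter
#' panel.
#'
#' @param t_map Numeric vector or `contrast_result` over the panel's regions.
#' @param panel Panel as produced by [generate_annotation_panel()]: list with
#'   `values` (regions x maps) and `info` (`map`, `class`).
#' @param ensemble A `spin_ensemble`.
#' @return Tibble with one row per map: `map`, `class`, `r`, `p_spin`,
#'   `p_bonferroni`, `significant`.
#' @export
panel_correlations <- function(t_map, panel, ensemble) {
  check_panel(panel)
  if (inherits(t_map, "contrast_result")) t_map <- t_map$t
  res <- purrr::map_dfr(seq_len(ncol(panel$values)), function(m) {
    spin_correlation_test(t_map, panel$values[, m], ensemble)
  })
  out <- dplyr::bind_cols(panel$info, res)
  out$p_bonferroni <- adjust_bonferroni(out$p_spin, m = nrow(out))
  out$significant <- out$p_bonferroni < 0.05
  out
}

#' Excitatory/inhibitory ratio map from an annotation panel
#'
#' z-scores every map across regions (population SD), averages the z-scores
#' of the excitatory maps and of the inhibitory maps per region, and returns
#' their ratio. Regions whose mean inhibitory z-score is within `eps` of
#' zero are flagged unstable rather than dropped.
#'
#' @param panel Panel with at least one map of class "excitatory" and one of
#'   class "inhibitory".
#' @param eps Denominator magnitude below which a region is flagged.
#' @return Tibble with `region_id`, `excitatory` and `inhibitory` mean
#'   z-scores, `value` (the ratio), and `unstable`.
#' @export
ei_ratio <- function(panel, eps = 1e-6) {
  check_panel(panel)
  exc <- which(panel$info$class == "excitatory")
  inh <- which(panel$info$class == "inhibitory")
  if (!length(exc) || !length(inh)) {
    abort("panel needs at least one excitatory and one inhibitory map",
          class = "mindgrad_invalid_panel")
  }
  Z <- apply(panel$values, 2, zscore_pop, what = "annotation map")
  E <- unname(rowMeans(Z[, exc, drop = FALSE]))
  I <- unname(rowMeans(Z[, inh, drop = FALSE]))
  ids <- rownames(panel$values)
  tibble::tibble(
    region_id = if (!is.null(ids)) as.integer(ids) else seq_along(E),
    excitatory = E, inhibitory = I,
    value = E / I, unstable = abs(I) < eps
  )
}
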