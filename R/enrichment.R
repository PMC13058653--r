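# Random-gene null-ratio enrichment of a gene list against labelled gene
# classes (synthetic cell types / cortical layers).

#' Null-ratio enrichment of a gene set against gene classes
#'
#' For each class, the observed statistic is the fraction of the gene set
#' belonging to the class. The null distribution is the same fraction for
#' `n_null` size-matched random draws from the background, giving
#' `p_enrich = (1 + #\{null >= obs\}) / (1 + n_null)` and the mirrored tail
#' `p_deplete`; both are BH-FDR corrected across classes.
#'
#' @param gene_set Character vector of gene ids (subset of `background`).
#' @param gene_classes Tibble with `gene_id` and `class` (a gene may appear
#'   in several classes).
#' @param background Character vector: the gene universe to resample from
#'   (conventionally all genes in the expression matrix).
#' @param n_null Number of random draws (>= 100; reference analyses use
#'   10,000).
#' @param seed Integer seed.
#' @return Tibble with one row per class: `class`, `n_class`, `ratio`,
#'   `null_mean`, `null_q25`, `null_q75`, `p_enrich`, `p_deplete`,
#'   `q_enrich`, `q_deplete`.
#' @export
null_ratio_enrichment <- function(gene_set, gene_classes, background,
                                  n_null = 1000L, seed = 1L) {
  n_null <- check_count(n_null, "n_null", lower = 100L)
  if (!length(gene_set)) {
    abort("gene_set is empty", class = "mindgrad_invalid_argument")
  }
  if (!all(gene_set %in% background)) {
    abort("gene_set must be a subset of the background",
          class = "mindgrad_invalid_argument")
  }
  if (!all(c("gene_id", "class") %in% names(gene_classes))) {
    abort("gene_classes must have columns gene_id and class",
          class = "mindgrad_invalid_argument")
  }
  classes <- sort(unique(gene_classes$class))
  members <- lapply(classes, function(cl) {
    unique(gene_classes$gene_id[gene_classes$class == cl])
  })
  n_set <- length(gene_set)
  obs <- vapply(members, function(g) mean(gene_set %in% g), numeric(1))

  null_ratios <- eval_with_seed(seed, {
    out <- matrix(0, n_null, length(classes))
    for (b in seq_len(n_null)) {
      draw <- sample(background, n_set, replace = FALSE)
      out[b, ] <- vapply(members, function(g) mean(draw %in% g), numeric(1))
    }
    out
  })

  p_enrich <- (1 + colSums(null_ratios >= rep(obs, each = n_null))) /
    (1 + n_null)
  p_deplete <- (1 + colSums(null_ratios <= rep(obs, each = n_null))) /
    (1 + n_null)
  tibble::tibble(
    class = classes,
    n_class = lengths(members),
    ratio = obs,
    null_mean = colMeans(null_ratios),
    null_q25 = apply(null_ratios, 2, quantile, 0.25),
    null_q75 = apply(null_ratios, 2, quantile, 0.75),
    p_enrich = p_enrich, p_deplete = p_deplete,
    q_enrich = bh_fdr(p_enrich), q_deplete = bh_fdr(p_deplete)
  )
}
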