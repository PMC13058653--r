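# MIND (Morphometric Inverse Divergence) similarity networks: z-scored
# vertex features -> per-region multivariate distributions -> symmetrized
# k-NN KL divergence -> similarity in (0, 1].

#' Standardize vertex features across the whole cortex
#'
#' z-scores each morphometric feature across ALL vertices of a subject (not
#' per region), using the population SD. This puts the five features on a
#' common scale before regional distributions are compared.
#'
#' @param vertices Tibble with columns `subject_id`, `vertex_id`,
#'   `region_id`, and the feature columns `CT`, `GM`, `SA`, `MC`, `SD`.
#' @return The same tibble with standardized feature columns (per subject).
#' @export
standardize_features <- function(vertices) {
  feats <- mind_features()
  missing <- setdiff(feats, names(vertices))
  if (length(missing)) {
    abort(paste("missing feature columns:", paste(missing, collapse = ", ")),
          class = "mindgrad_invalid_argument")
  }
  vertices |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(feats),
      \(x) zscore_pop(x, what = dplyr::cur_column())
    )) |>
    dplyr::ungroup()
}

#' k-nearest-neighbour Kullback-Leibler divergence estimate
#'
#' Nonparametric estimate of D(A||B) between two d-dimensional samples using
#' k-th nearest-neighbour distances (Wang-Kulkarni-Verdu estimator):
#' `(d/n_a) * sum(log(nu_k / rho_k)) + log(n_b / (n_a - 1))`, where `rho_k`
#' is the k-NN distance of each point of A within A (self excluded) and
#' `nu_k` its k-NN distance into B. Negative estimates are clipped at zero.
#'
#' @param sample_a,sample_b Numeric matrices (points x dimensions) with the
#'   same number of columns.
#' @param k Neighbour order (default 1, the reference MIND choice).
#' @return Nonnegative scalar estimate of D(A||B).
#' @export
kl_divergence_knn <- function(sample_a, sample_b, k = 1L) {
  sample_a <- as.matrix(sample_a)
  sample_b <- as.matrix(sample_b)
  k <- check_count(k, "k")
  if (ncol(sample_a) != ncol(sample_b)) {
    abort("samples must have the same dimension",
          class = "mindgrad_dimension_error")
  }
  n_a <- nrow(sample_a); n_b <- nrow(sample_b); d <- ncol(sample_a)
  if (n_a <= k || n_b <= k) {
    abort(sprintf("need more than k = %d points in each sample (got %d, %d)",
                  k, n_a, n_b),
          class = "mindgrad_insufficient_sample")
  }
  rho <- .knn_kth_dist(sample_a, sample_a, k, TRUE)
  nu <- .knn_kth_dist(sample_a, sample_b, k, FALSE)
  est <- (d / n_a) * sum(log(nu / rho)) + log(n_b / (n_a - 1))
  max(est, 0)
}

#' MIND similarity between two regional samples
#'
#' `MIND = 1 / (1 + Dsym)` with `Dsym = D(A||B) + D(B||A)` estimated by
#' [kl_divergence_knn()]; symmetric by construction and bounded in (0, 1].
#'
#' @inheritParams kl_divergence_knn
#' @return Similarity in (0, 1].
#' @export
mind_similarity <- function(sample_a, sample_b, k = 1L) {
  dsym <- kl_divergence_knn(sample_a, sample_b, k) +
    kl_divergence_knn(sample_b, sample_a, k)
  1 / (1 + dsym)
}

#' Build a subject's MIND similarity matrix
#'
#' Computes the symmetric regions-by-regions MIND matrix from a standardized
#' vertex table: every region pair is compared once via the symmetrized k-NN
#' KL divergence and mirrored; the diagonal (self-similarity) is zero by
#' policy and excluded from the weighted degree, which is the mean of each
#' row's off-diagonal entries.
#'
#' @param vertices Standardized vertex tibble for one subject (see
#'   [standardize_features()]).
#' @param parcellation Parcellation tibble; all its regions must be present.
#' @param k Neighbour order for the KL estimator.
#' @return An object of class `mind_matrix`: list with `values` (R x R
#'   matrix, region ids as dimnames), `degree` (named vector), `subject_id`,
#'   `k`.
#' @export
build_mind_matrix <- function(vertices, parcellation, k = 1L) {
  check_parcellation(parcellation)
  subject_id <- unique(vertices$subject_id)
  if (length(subject_id) != 1L) {
    abort("`vertices` must contain exactly one subject",
          class = "mindgrad_invalid_argument")
  }
  ids <- parcellation$region_id
  present <- unique(vertices$region_id)
  miss <- setdiff(ids, present)
  if (length(miss)) {
    abort(paste("vertex table is missing regions:",
                paste(head(miss, 10), collapse = ", ")),
          class = "mindgrad_incomplete_parcellation")
  }
  feats <- mind_features()
  k <- check_count(k, "k")
  reg <- factor(vertices$region_id, levels = ids)
  ord <- order(as.integer(reg))
  X <- as.matrix(vertices[ord, feats])
  sizes <- tabulate(as.integer(reg), nbins = length(ids))

  R <- length(ids)
  M <- .mind_matrix_cpp(X, sizes, k)
  dimnames(M) <- list(ids, ids)
  degree <- rowSums(M) / (R - 1)
  structure(
    list(values = M, degree = setNames(degree, ids),
         subject_id = subject_id, k = k),
    class = "mind_matrix"
  )
}

#' @export
print.mind_matrix <- function(x, ...) {
  cat(sprintf("<mind_matrix> subject %s: %d regions, k = %d\n",
              x$subject_id, nrow(x$values), x$k))
  cat(sprintf("  off-diagonal similarity range: [%.3f, %.3f]\n",
              min(x$values[upper.tri(x$values)]),
              max(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Tidy a MIND matrix into an edge list
#'
#' @param x A `mind_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per unordered region pair: `region_a`,
#'   `region_b`, `similarity`.
#' @export
tidy.mind_matrix <- function(x, ...) {
  M <- x$values
  ut <- which(upper.tri(M), arr.ind = TRUE)
  ids <- as.integer(rownames(M))
  tibble::tibble(
    subject_id = x$subject_id,
    region_a = ids[ut[, 1]],
    region_b = ids[ut[, 2]],
    similarity = M[ut]
  )
}

#' One-row summary of a MIND matrix
#' @param x A `mind_matrix`.
#' @param ... Unused.
#' @export
glance.mind_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  tibble::tibble(
    subject_id = x$subject_id, n_regions = nrow(x$values), k = x$k,
    mean_similarity = mean(off), min_similarity = min(off),
    max_similarity = max(off)
  )
}

#' Heatmap of a MIND similarity matrix
#' @param object A `mind_matrix`.
#' @param ... Unused.
#' @export
autoplot.mind_matrix <- function(object, ...) {
  M <- object$values
  df <- tidyr::expand_grid(region_a = as.integer(rownames(M)),
                           region_b = as.integer(colnames(M)))
  df$similarity <- as.vector(t(M))
  ggplot2::ggplot(df, ggplot2::aes(.data$region_b, .data$region_a,
                                   fill = .data$similarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("MIND similarity, subject %s",
                                  object$subject_id)) +
    ggplot2::coord_fixed()
}

#' Build MIND matrices for every subject of a cohort
#'
#' Convenience wrapper: standardizes features per subject and maps
#' [build_mind_matrix()] over subjects.
#'
#' @param vertices Vertex tibble for one or more subjects (raw units).
#' @inheritParams build_mind_matrix
#' @return Named list of `mind_matrix` objects (one per subject).
#' @export
build_cohort_mind <- function(vertices, parcellation, k = 1L) {
  std <- standardize_features(vertices)
  split(std, std$subject_id) |>
    purrr::map(build_mind_matrix, parcellation = parcellation, k = k)
}
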