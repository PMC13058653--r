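# Diffusion-map gradients of MIND networks: row thresholding, normalized
# angle affinity, density-normalized diffusion embedding, group template,
# Procrustes alignment of individual embeddings.

as_similarity_matrix <- function(x) {
  if (inherits(x, "mind_matrix")) x$values else as.matrix(x)
}

#' Keep the top fraction of each row of a similarity matrix
#'
#' Per row, the `ceiling(fraction * (R - 1))` largest off-diagonal entries
#' are retained and all other entries set to zero (the result is generally
#' asymmetric). Ties at the cutoff are broken in favour of the lower region
#' index, which makes the operation deterministic.
#'
#' @param matrix A `mind_matrix` or plain R x R numeric matrix.
#' @param fraction Fraction of off-diagonal entries kept per row, in (0, 1].
#'   The default 0.1 keeps the top 10% per row.
#' @return R x R nonnegative matrix with zeroed diagonal.
#' @export
threshold_rows <- function(matrix, fraction = 0.1) {
  M <- as_similarity_matrix(matrix)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1]", class = "mindgrad_invalid_argument")
  }
  R <- nrow(M)
  keep <- ceiling(fraction * (R - 1))
  out <- matrix(0, R, R, dimnames = dimnames(M))
  for (i in seq_len(R)) {
    row <- M[i, ]
    row[i] <- -Inf
    ord <- order(row, seq_len(R), decreasing = c(TRUE, FALSE), method = "radix")
    idx <- ord[seq_len(keep)]
    out[i, idx] <- M[i, idx]
  }
  out
}

#' Normalized-angle affinity between connectivity rows
#'
#' `a_ij = 1 - acos(cosine(row_i, row_j)) / pi`, computed between the rows
#' of a (thresholded) nonnegative matrix. For nonnegative rows the affinity
#' lies in [0.5, 1]; the diagonal is 1.
#'
#' @param thresholded R x R nonnegative matrix (e.g. from
#'   [threshold_rows()]). The diagonal column enters the cosine as-is.
#' @return Symmetric R x R affinity matrix.
#' @export
normalized_angle_affinity <- function(thresholded) {
  M <- as.matrix(thresholded)
  norms <- sqrt(rowSums(M^2))
  if (any(norms == 0)) {
    abort(paste("all-zero rows at indices:",
                paste(head(which(norms == 0), 10), collapse = ", ")),
          class = "mindgrad_degenerate_region")
  }
  cosine <- tcrossprod(M / norms)
  cosine <- pmin(pmax(cosine, -1), 1)
  A <- 1 - acos(cosine) / pi
  (A + t(A)) / 2
}

connected_graph <- function(A) {
  R <- nrow(A)
  seen <- logical(R)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nb <- which(colSums(A[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

new_gradient_set <- function(components, lambdas, alpha, threshold_fraction,
                             aligned_to = NA_character_) {
  structure(
    list(components = components, lambdas = lambdas,
         variance_explained = lambdas / sum(lambdas),
         alpha = alpha, threshold_fraction = threshold_fraction,
         aligned_to = aligned_to),
    class = "gradient_set"
  )
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Density-normalizes the affinity (`W_a = D^-alpha W D^-alpha`), forms the
#' Markov operator `P = D_a^-1 W_a`, eigendecomposes it through the
#' equivalent symmetric problem, drops the trivial constant eigenvector
#' (eigenvalue 1), and returns the leading nontrivial components scaled by
#' their eigenvalues (diffusion time 0 convention). `alpha = 0.5` balances
#' the influence of sampling density and is the conventional choice for
#' connectivity gradients. Variance explained is each retained eigenvalue
#' over the sum of retained nontrivial eigenvalues.
#'
#' @param affinity Symmetric nonnegative matrix with a connected graph.
#' @param alpha Density-normalization exponent in [0, 1].
#' @param n_components Number of nontrivial components to retain.
#' @return A `gradient_set`: `components` (R x k, eigenvalue-scaled),
#'   `lambdas`, `variance_explained`, `alpha`, `threshold_fraction`.
#' @export
diffusion_embed <- function(affinity, alpha = 0.5, n_components = 10L) {
  A <- as.matrix(affinity)
  n_components <- check_count(n_components, "n_components")
  check_scalar_number(alpha, "alpha", 0, 1)
  if (!isSymmetric(A, tol = 1e-9)) {
    abort("affinity must be symmetric", class = "mindgrad_invalid_argument")
  }
  if (any(A < 0)) {
    abort("affinity must be nonnegative", class = "mindgrad_invalid_argument")
  }
  if (!connected_graph(A)) {
    abort("affinity graph is disconnected", class = "mindgrad_connectivity_error")
  }
  R <- nrow(A)
  if (n_components > R - 1L) {
    abort("n_components must be < number of regions",
          class = "mindgrad_invalid_argument")
  }
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  da <- rowSums(W)
  S <- W / outer(sqrt(da), sqrt(da))
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  # trivial component: eigenvalue 1, constant after D^{-1/2} scaling
  lambdas <- eig$values[2:(n_components + 1)]
  psi <- eig$vectors[, 2:(n_components + 1), drop = FALSE] / sqrt(da)
  comps <- sweep(psi, 2, lambdas, "*")
  rownames(comps) <- rownames(A)
  colnames(comps) <- paste0("g", seq_len(n_components))
  new_gradient_set(comps, lambdas, alpha, NA_real_)
}

#' Embed a single MIND matrix
#'
#' Threshold -> normalized-angle affinity -> diffusion embedding in one call.
#'
#' @inheritParams threshold_rows
#' @inheritParams diffusion_embed
#' @export
embed_mind <- function(matrix, fraction = 0.1, alpha = 0.5,
                       n_components = 10L) {
  thr <- threshold_rows(matrix, fraction)
  gs <- diffusion_embed(normalized_angle_affinity(thr), alpha, n_components)
  gs$threshold_fraction <- fraction
  gs
}

#' Build a group-level gradient template
#'
#' Averages the MIND matrices element-wise across all subjects (cases and
#' controls pooled), embeds the mean matrix, and fixes the eigenvector sign
#' indeterminacy by orienting every component so its mean over an anchor set
#' (the highest-degree decile of regions in the mean matrix) is positive.
#'
#' @param matrices List of `mind_matrix` objects (or plain matrices) on a
#'   common parcellation.
#' @inheritParams embed_mind
#' @return A `gradient_set` with `aligned_to = "template"`.
#' @export
build_group_template <- function(matrices, fraction = 0.1, alpha = 0.5,
                                 n_components = 10L) {
  if (length(matrices) < 2L) {
    abort("need at least 2 subjects to build a template",
          class = "mindgrad_invalid_argument")
  }
  mats <- lapply(matrices, as_similarity_matrix)
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1L) {
    abort("MIND matrices differ in size", class = "mindgrad_dimension_error")
  }
  mean_mat <- Reduce(`+`, mats) / length(mats)
  gs <- embed_mind(mean_mat, fraction, alpha, n_components)
  degree <- rowSums(mean_mat) / (nrow(mean_mat) - 1)
  anchors <- order(degree, decreasing = TRUE)[
    seq_len(max(1L, floor(nrow(mean_mat) / 10)))]
  flip <- colMeans(gs$components[anchors, , drop = FALSE]) < 0
  gs$components[, flip] <- -gs$components[, flip]
  gs$aligned_to <- "template"
  gs
}

#' Procrustes-align an individual gradient set to a template
#'
#' Finds the orthogonal rotation (no scaling; translation limited to column
#' centering, with the template's column means restored afterwards)
#' minimizing the Frobenius distance between the individual's components and
#' the template's, and applies it. Variance explained is carried over from
#' the unaligned solution. Individuals inherit the template's sign
#' orientation through the rotation.
#'
#' @param individual,template `gradient_set` objects with identical
#'   dimensions.
#' @return The aligned `gradient_set`.
#' @export
procrustes_align <- function(individual, template) {
  X <- individual$components
  Tm <- template$components
  if (!all(dim(X) == dim(Tm))) {
    abort("individual and template have different dimensions",
          class = "mindgrad_dimension_error")
  }
  Xc <- sweep(X, 2, colMeans(X))
  Tc <- sweep(Tm, 2, colMeans(Tm))
  M <- crossprod(Xc, Tc)
  sv <- svd(M)
  if (min(sv$d) < 1e-12 * max(sv$d)) {
    warn("rank-deficient gradient set; using identity rotation")
    Q <- diag(ncol(X))
  } else {
    Q <- sv$u %*% t(sv$v)
  }
  aligned <- sweep(Xc %*% Q, 2, colMeans(Tm), "+")
  dimnames(aligned) <- dimnames(X)
  out <- individual
  out$components <- aligned
  out$aligned_to <- "template"
  out
}

#' Compute aligned individual gradients for a cohort
#'
#' Builds the group template from all subjects' MIND matrices, embeds each
#' subject with the same parameters, aligns every embedding to the template
#' by Procrustes rotation, and returns the pieces downstream stages need.
#'
#' @inheritParams build_group_template
#' @return List with `template` (`gradient_set`), `individuals` (named list
#'   of aligned `gradient_set`s), and `gradient1` (subjects x regions matrix
#'   of principal-gradient scores, region ids as column names).
#' @export
fit_cohort_gradients <- function(matrices, fraction = 0.1, alpha = 0.5,
                                 n_components = 10L) {
  template <- build_group_template(matrices, fraction, alpha, n_components)
  individuals <- lapply(matrices, function(m) {
    procrustes_align(embed_mind(m, fraction, alpha, n_components), template)
  })
  g1 <- do.call(rbind, lapply(individuals, function(g) g$components[, 1]))
  rownames(g1) <- names(matrices)
  list(template = template, individuals = individuals, gradient1 = g1)
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf(
    "<gradient_set> %d regions x %d components (alpha = %s%s)\n",
    nrow(x$components), ncol(x$components), format(x$alpha),
    if (!is.na(x$aligned_to)) paste0(", aligned to ", x$aligned_to) else ""))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * head(x$variance_explained, 5)),
            collapse = " "), "...\n")
  invisible(x)
}

#' Tidy gradients into long format
#' @param x A `gradient_set`.
#' @param ... Unused.
#' @return Tibble with `region_id`, `component`, `score`.
#' @export
tidy.gradient_set <- function(x, ...) {
  C <- x$components
  tibble::tibble(
    region_id = rep(as.integer(rownames(C)), ncol(C)),
    component = rep(seq_len(ncol(C)), each = nrow(C)),
    score = as.vector(C)
  )
}

#' One-row gradient summary
#' @param x A `gradient_set`.
#' @param ... Unused.
#' @export
glance.gradient_set <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x$components), n_components = ncol(x$components),
    alpha = x$alpha, threshold_fraction = x$threshold_fraction,
    var_explained_g1 = x$variance_explained[1],
    aligned = !is.na(x$aligned_to)
  )
}

#' Scree plot of gradient variance explained
#' @param object A `gradient_set`.
#' @param ... Unused.
#' @export
autoplot.gradient_set <- function(object, ...) {
  df <- tibble::tibble(component = seq_along(object$variance_explained),
                       variance_explained = object$variance_explained)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$variance_explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "Gradient", y = "Variance explained",
                  title = "Diffusion-map gradient spectrum")
}
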