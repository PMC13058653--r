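# Spin-permutation null models for parcellated spherical maps. Random
# rotations are applied to the left-hemisphere centroids and their x-mirrored
# counterparts to the right hemisphere, and each region is reassigned to the
# nearest rotated centroid (duplicates permitted), preserving spatial
# autocorrelation while breaking map-map alignment.

# Haar-uniform random rotation: QR of a Gaussian matrix with the sign of
# diag(R) absorbed, then determinant forced to +1.
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Build a spin-permutation ensemble for a parcellation
#'
#' Draws `n_spins` uniform random rotations; each rotation is applied to the
#' left-hemisphere centroids and its x-mirrored version to the right
#' hemisphere, so paired regions rotate coherently. Every region is then
#' reassigned to the region whose rotated centroid lies nearest (within
#' hemisphere, duplicates permitted).
#'
#' @param parcellation Parcellation tibble with unit-sphere centroids.
#' @param n_spins Number of spins (the reference analyses use 10,000).
#' @param seed Integer seed.
#' @return A `spin_ensemble`: `permutations` (n_spins x R integer matrix;
#'   row s maps a map `x` to `x[permutations[s, ]]`), `n_spins`, `seed`,
#'   `region_id`, `hemisphere`.
#' @export
build_spin_ensemble <- function(parcellation, n_spins = 1000L, seed = 1L) {
  check_parcellation(parcellation)
  n_spins <- check_count(n_spins, "n_spins")
  cent <- parcellation_centroids(parcellation)
  hemi <- parcellation$hemisphere
  R <- nrow(cent)
  mirror <- diag(c(-1, 1, 1))
  sides <- split(seq_len(R), hemi)

  perms <- eval_with_seed(seed, {
    out <- matrix(0L, n_spins, R)
    for (s in seq_len(n_spins)) {
      Q <- random_rotation()
      for (h in names(sides)) {
        idx <- sides[[h]]
        Qh <- if (h == "L") Q else mirror %*% Q %*% mirror
        rot <- cent[idx, , drop = FALSE] %*% t(Qh)
        # nearest rotated centroid to each original centroid; maximizing the
        # dot product is equivalent on the unit sphere
        sim <- cent[idx, , drop = FALSE] %*% t(rot)
        out[s, idx] <- idx[max.col(sim, ties.method = "first")]
      }
    }
    out
  })
  structure(
    list(permutations = perms, n_spins = n_spins, seed = seed,
         region_id = parcellation$region_id, hemisphere = hemi),
    class = "spin_ensemble"
  )
}

#' @export
print.spin_ensemble <- function(x, ...) {
  cat(sprintf("<spin_ensemble> %d spins x %d regions (seed %d)\n",
              x$n_spins, length(x$region_id), x$seed))
  invisible(x)
}

#' Restrict a spin ensemble to a subset of regions
#'
#' Spins never cross hemispheres, so an ensemble restricted to one
#' hemisphere's regions is itself a valid ensemble for maps defined only on
#' those regions (used for left-hemisphere transcriptomic maps).
#'
#' @param ensemble A `spin_ensemble`.
#' @param region_ids Region ids to keep (must be closed under the spins,
#'   e.g. one hemisphere).
#' @export
subset_spin_ensemble <- function(ensemble, region_ids) {
  idx <- match(region_ids, ensemble$region_id)
  if (anyNA(idx)) {
    abort("region_ids not all present in the ensemble",
          class = "mindgrad_invalid_argument")
  }
  sub <- ensemble$permutations[, idx, drop = FALSE]
  remapped <- match(as.vector(sub), idx)
  if (anyNA(remapped)) {
    abort("region subset is not closed under the spins (mixed hemispheres?)",
          class = "mindgrad_invalid_argument")
  }
  structure(
    list(permutations = matrix(remapped, nrow(sub), ncol(sub)),
         n_spins = ensemble$n_spins, seed = ensemble$seed,
         region_id = ensemble$region_id[idx],
         hemisphere = ensemble$hemisphere[idx]),
    class = "spin_ensemble"
  )
}

# Null correlations of each spun version of x with fixed y, vectorised.
spin_null_correlations <- function(x, y, ensemble) {
  N <- matrix(x[ensemble$permutations], ensemble$n_spins,
              length(ensemble$region_id))
  Nc <- N - rowMeans(N)
  yc <- y - mean(y)
  as.numeric(Nc %*% yc) / sqrt(rowSums(Nc^2) * sum(yc^2))
}

#' Spin-permutation test of the correlation between two region maps
#'
#' Pearson correlation between `map_x` and `map_y` with a two-sided spin
#' p-value: the first map is permuted by the ensemble while the second stays
#' fixed, and `p = (1 + #\{|r_null| >= |r_obs|\}) / (1 + n_spins)`, so p is
#' never exactly zero.
#'
#' @param map_x,map_y Numeric vectors (or tibbles with `region_id`,`value`)
#'   over the ensemble's regions. `map_x` is the map being permuted
#'   (conventionally the statistical map).
#' @param ensemble A `spin_ensemble` on the same parcellation.
#' @return Tibble with `r` and `p_spin`.
#' @export
spin_correlation_test <- function(map_x, map_y, ensemble) {
  x <- region_values(map_x, ensemble$region_id, "map_x")
  y <- region_values(map_y, ensemble$region_id, "map_y")
  if (pop_sd(x) == 0 || pop_sd(y) == 0) {
    abort("correlation undefined for a constant map",
          class = "mindgrad_undefined_correlation")
  }
  r_obs <- cor(x, y)
  r_null <- spin_null_correlations(x, y, ensemble)
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + ensemble$n_spins)
  tibble::tibble(r = r_obs, p_spin = p)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, m * p)`; `m` defaults to the number of p-values but can
#' be larger when the family includes tests not in the vector.
#'
#' @param p_values Numeric p-values in [0, 1].
#' @param m Family size.
#' @export
adjust_bonferroni <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "mindgrad_invalid_argument")
  }
  m <- check_count(m, "m")
  pmin(1, m * p_values)
}
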