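# Synthetic study generator: spherical parcellations, vertex-level cohorts
# with planted group effects, spatially autocorrelated annotation maps, and
# gene-expression matrices with a planted spatial loading.

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards so
# generators are reproducible without clobbering the session RNG.
eval_with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a mirrored spherical parcellation
#'
#' Places `R_per_hemisphere` region centroids per hemisphere on the unit
#' sphere using a Fibonacci lattice, mirrors the right hemisphere in the
#' x-coordinate so spin rotations can be applied in paired form, and assigns
#' spatially contiguous 7-level network labels (latitude bands, emulating
#' seven intrinsic functional networks) and 7-level cytoarchitectonic class
#' labels (longitude sectors). Vertex counts per region are drawn uniformly
#' from `vertex_range`: real ~5 cm2 cortical parcels contain a few hundred
#' surface vertices, which also keeps nearest-neighbour divergence estimation
#' well conditioned.
#'
#' @param R_per_hemisphere Number of regions per hemisphere (>= 4). The
#'   default, 154, gives a 308-region cortex matching the scale of the
#'   parcellations used with MIND networks.
#' @param seed Integer seed controlling vertex counts.
#' @param vertex_range Length-2 integer range for per-region vertex counts.
#' @return A tibble with columns `region_id`, `hemisphere` ("L"/"R"), unit
#'   centroid coordinates `x`, `y`, `z`, `network_label`, `class_label`,
#'   `n_vertices`.
#' @export
generate_parcellation <- function(R_per_hemisphere = 154L, seed = 1L,
                                  vertex_range = c(200L, 500L)) {
  R_per_hemisphere <- check_count(R_per_hemisphere, "R_per_hemisphere", lower = 4L)
  check_count(seed, "seed", lower = -.Machine$integer.max)
  n <- R_per_hemisphere
  i <- seq_len(n) - 0.5
  zc <- 1 - 2 * i / n
  golden <- pi * (3 - sqrt(5))
  phi <- (seq_len(n) - 1) * golden
  r_xy <- sqrt(pmax(0, 1 - zc^2))
  left <- cbind(x = r_xy * cos(phi), y = r_xy * sin(phi), z = zc)
  # contiguous latitude bands -> network, longitude sectors -> class
  network <- as.integer(ceiling(7 * i / n))
  class_lab <- as.integer(floor(7 * ((phi %% (2 * pi)) / (2 * pi))) + 1L)

  n_vert <- eval_with_seed(seed, {
    sample(seq.int(vertex_range[1], vertex_range[2]), 2L * n, replace = TRUE)
  })

  tibble::tibble(
    region_id = seq_len(2L * n),
    hemisphere = rep(c("L", "R"), each = n),
    x = c(left[, "x"], -left[, "x"]),
    y = rep(left[, "y"], 2L),
    z = rep(left[, "z"], 2L),
    network_label = rep(network, 2L),
    class_label = rep(class_lab, 2L),
    n_vertices = n_vert
  )
}

parcellation_centroids <- function(parcellation) {
  as.matrix(parcellation[, c("x", "y", "z")])
}

# Coordinates for whole-brain Gaussian-process draws: the right hemisphere is
# reflected back onto the left so homotopic regions coincide and generated
# maps are bilaterally mirror-symmetric. This matches both the anatomy the
# generator emulates (molecular and morphometric maps are strongly
# homotopically correlated) and the exchangeability assumption of
# mirrored-pair spin rotations.
mirrored_centroids <- function(parcellation) {
  cent <- parcellation_centroids(parcellation)
  right <- parcellation$hemisphere == "R"
  cent[right, 1] <- -cent[right, 1]
  cent
}

check_parcellation <- function(parcellation) {
  stopifnot(is.data.frame(parcellation))
  needed <- c("region_id", "hemisphere", "x", "y", "z")
  if (!all(needed %in% names(parcellation))) {
    abort("parcellation must have columns region_id, hemisphere, x, y, z",
          class = "mindgrad_invalid_argument")
  }
  norms <- sqrt(rowSums(parcellation_centroids(parcellation)^2))
  if (any(abs(norms - 1) > 1e-9)) {
    abort("parcellation centroids must lie on the unit sphere",
          class = "mindgrad_invalid_parcellation")
  }
  if (anyDuplicated(parcellation$region_id)) {
    abort("region_id values must be unique", class = "mindgrad_invalid_argument")
  }
  invisible(parcellation)
}

# Feature names used throughout: cortical thickness, gray-matter volume,
# surface area, mean curvature, sulcal depth.
mind_features <- function() c("CT", "GM", "SA", "MC", "SD")

#' Generate a synthetic vertex-level cohort with a planted group effect
#'
#' Each region carries a fixed 5-dimensional Gaussian over the morphometric
#' features (CT, GM, SA, MC, SD): region mean vectors and per-feature scales
#' vary smoothly over the sphere (squared-exponential Gaussian process on
#' chordal distance), sharing one cross-feature correlation structure.
#' Subjects add a global per-feature random offset, and case subjects have
#' every feature mean in `effect_regions` shifted by `effect_size` pooled
#' (region) standard deviations. Covariates mimic an adult cohort: age uniform
#' on 21-50 years, sex coded 0/1, education normal(14, 2) truncated at >= 8
#' years.
#'
#' @param parcellation Output of [generate_parcellation()].
#' @param n_cases,n_controls Group sizes.
#' @param effect_regions Integer region ids receiving the case shift.
#' @param effect_size Case shift in pooled-SD units (>= 0).
#' @param subject_sd SD of the global per-subject feature offset, in units of
#'   the feature's regional SD.
#' @param seed Integer seed.
#' @return A list with `vertices` (tibble: subject_id, vertex_id, region_id,
#'   CT, GM, SA, MC, SD) and `covariates` (tibble: subject_id, group, age,
#'   sex, education).
#' @export
generate_cohort <- function(parcellation, n_cases, n_controls,
                            effect_regions = integer(), effect_size = 0,
                            subject_sd = 0.2, seed = 1L) {
  check_parcellation(parcellation)
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  check_scalar_number(effect_size, "effect_size", lower = 0)
  if (length(effect_regions) &&
      !all(effect_regions %in% parcellation$region_id)) {
    abort("effect_regions must be region ids present in the parcellation",
          class = "mindgrad_invalid_argument")
  }
  feats <- mind_features()
  R <- nrow(parcellation)
  cent <- mirrored_centroids(parcellation)

  eval_with_seed(seed, {
    # region-level distributions, fixed for the whole cohort
    mu <- gp_sphere_draw(cent, lengthscale = 0.5, n_draws = 5L) * 1.5
    sd_r <- exp(0.3 * gp_sphere_draw(cent, lengthscale = 0.5, n_draws = 5L))
    W <- matrix(rnorm(5 * 8), 5, 8)
    C <- stats::cov2cor(tcrossprod(W) + 5 * diag(5))

    n_sub <- n_cases + n_controls
    group <- rep(c("case", "control"), c(n_cases, n_controls))
    subject_id <- sprintf("sub-%03d", seq_len(n_sub))
    age <- runif(n_sub, 21, 50)
    sex <- rbinom(n_sub, 1L, 0.5)
    education <- pmax(8, rnorm(n_sub, 14, 2))
    offsets <- matrix(rnorm(n_sub * 5, sd = subject_sd), n_sub, 5)

    eff_idx <- match(effect_regions, parcellation$region_id)
    nv <- parcellation$n_vertices
    vert_list <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      blocks <- vector("list", R)
      for (r in seq_len(R)) {
        Sig_chol <- chol(diag(sd_r[r, ]) %*% C %*% diag(sd_r[r, ]))
        m <- mu[r, ] + offsets[s, ] * sd_r[r, ]
        if (group[s] == "case" && r %in% eff_idx) {
          m <- m + effect_size * sd_r[r, ]
        }
        Z <- matrix(rnorm(nv[r] * 5), nv[r], 5) %*% Sig_chol
        blocks[[r]] <- sweep(Z, 2, m, "+")
      }
      X <- do.call(rbind, blocks)
      colnames(X) <- feats
      vert_list[[s]] <- tibble::tibble(
        subject_id = subject_id[s],
        vertex_id = seq_len(nrow(X)),
        region_id = rep(parcellation$region_id, nv)
      ) |> dplyr::bind_cols(tibble::as_tibble(X))
    }
    list(
      vertices = dplyr::bind_rows(vert_list),
      covariates = tibble::tibble(subject_id, group, age, sex, education)
    )
  })
}

#' Simulate principal-gradient scores for a cohort
#'
#' Generates a subjects-by-regions matrix of principal-gradient scores
#' directly at the gradient level: a smooth base map shared by all subjects,
#' linear age and sex effects, i.i.d. subject noise, and a planted case shift
#' of `effect_size` noise-SD units in `effect_regions`. This is the working
#' model for power and calibration studies of the region-wise contrast stage,
#' where the quantity of interest is defined on gradient scores rather than
#' on vertices.
#'
#' @inheritParams generate_cohort
#' @param noise_sd Subject-level noise SD (the unit of `effect_size`).
#' @param beta_age,beta_sex Linear covariate effects on every region.
#' @return List with `gradient1` (numeric matrix, subjects x regions, region
#'   ids as column names) and `covariates` (tibble as in [generate_cohort()]).
#' @export
simulate_gradient_cohort <- function(parcellation, n_cases, n_controls,
                                     effect_regions = integer(),
                                     effect_size = 0, noise_sd = 1,
                                     beta_age = 0.01, beta_sex = 0.1,
                                     seed = 1L) {
  check_parcellation(parcellation)
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  check_scalar_number(effect_size, "effect_size", lower = 0)
  if (length(effect_regions) &&
      !all(effect_regions %in% parcellation$region_id)) {
    abort("effect_regions must be region ids present in the parcellation",
          class = "mindgrad_invalid_argument")
  }
  R <- nrow(parcellation)
  eval_with_seed(seed, {
    base <- as.numeric(gp_sphere_draw(mirrored_centroids(parcellation), 0.5))
    n_sub <- n_cases + n_controls
    group <- rep(c("case", "control"), c(n_cases, n_controls))
    age <- runif(n_sub, 21, 50)
    sex <- rbinom(n_sub, 1L, 0.5)
    education <- pmax(8, rnorm(n_sub, 14, 2))
    G <- matrix(base, n_sub, R, byrow = TRUE) +
      beta_age * (age - mean(age)) + beta_sex * sex +
      matrix(rnorm(n_sub * R, sd = noise_sd), n_sub, R)
    eff_idx <- match(effect_regions, parcellation$region_id)
    if (length(eff_idx)) {
      G[group == "case", eff_idx] <- G[group == "case", eff_idx] +
        effect_size * noise_sd
    }
    colnames(G) <- parcellation$region_id
    list(
      gradient1 = G,
      covariates = tibble::tibble(
        subject_id = sprintf("sub-%03d", seq_len(n_sub)),
        group, age, sex, education
      )
    )
  })
}

#' Generate a spatially autocorrelated annotation map
#'
#' Draws one Gaussian-process realisation over the parcellation centroids
#' with a squared-exponential kernel on chordal distance and z-scores it
#' across regions (population SD). Small `smoothness` approaches i.i.d.
#' noise; large `smoothness` approaches a constant map before z-scoring.
#'
#' @inheritParams generate_cohort
#' @param smoothness Kernel length-scale (> 0), in chordal-distance units on
#'   the unit sphere (2 is the sphere diameter).
#' @return Tibble with `region_id` and `value` (mean 0, population SD 1).
#' @export
generate_annotation_map <- function(parcellation, smoothness = 0.5, seed = 1L) {
  check_parcellation(parcellation)
  if (!is.numeric(smoothness) || smoothness <= 0) {
    abort("`smoothness` must be > 0", class = "mindgrad_invalid_argument")
  }
  vals <- eval_with_seed(seed, {
    as.numeric(gp_sphere_draw(mirrored_centroids(parcellation), smoothness,
                              nugget = 1e-6))
  })
  tibble::tibble(region_id = parcellation$region_id,
                 value = zscore_pop(vals, "annotation map"))
}

#' Generate a synthetic receptor/transporter annotation panel
#'
#' Produces `n_maps` independent smooth annotation maps with class labels
#' mirroring the multiple-testing burden of a 19-map neurotransmitter panel:
#' by default 8 excitatory, 7 inhibitory, and 4 "other" (transporter) maps.
#'
#' @inheritParams generate_annotation_map
#' @param n_maps Total number of maps.
#' @param n_excitatory,n_inhibitory Number of maps labelled excitatory /
#'   inhibitory; the remainder are labelled "other".
#' @return List with `values` (regions x maps matrix, map names as columns)
#'   and `info` (tibble: map, class).
#' @export
generate_annotation_panel <- function(parcellation, n_maps = 19L,
                                      n_excitatory = 8L, n_inhibitory = 7L,
                                      smoothness = 0.5, seed = 1L) {
  n_maps <- check_count(n_maps, "n_maps")
  n_excitatory <- check_count(n_excitatory, "n_excitatory", lower = 0L)
  n_inhibitory <- check_count(n_inhibitory, "n_inhibitory", lower = 0L)
  if (n_excitatory + n_inhibitory > n_maps) {
    abort("class counts exceed n_maps", class = "mindgrad_invalid_argument")
  }
  maps <- vapply(seq_len(n_maps), function(m) {
    generate_annotation_map(parcellation, smoothness, seed = seed + m)$value
  }, numeric(nrow(parcellation)))
  colnames(maps) <- sprintf("map_%02d", seq_len(n_maps))
  rownames(maps) <- parcellation$region_id
  cls <- rep("other", n_maps)
  cls[seq_len(n_excitatory)] <- "excitatory"
  cls[n_excitatory + seq_len(n_inhibitory)] <- "inhibitory"
  list(values = maps, info = tibble::tibble(map = colnames(maps), class = cls))
}

#' Generate a gene-expression matrix with a planted spatial loading
#'
#' Emulates a donor-atlas regional expression matrix restricted to the left
#' hemisphere. A fraction `loading_fraction` of genes load on `target_map`
#' (gene-specific signed coefficients plus noise); the remainder are purely
#' spatially smooth noise. Genes are assigned to `n_classes` synthetic cell
#' classes with loaded genes preferentially placed in `enriched_classes`, and
#' the matrix is z-scored per gene across regions.
#'
#' @param parcellation Parcellation; only hemisphere "L" rows are used.
#' @param n_genes Number of genes.
#' @param target_map Numeric vector (or tibble with `value`) over the left
#'   regions that loaded genes track.
#' @param loading_fraction Fraction of genes loaded on the target (0..1).
#' @param noise_sd Noise SD added to loaded genes.
#' @param n_classes Number of synthetic gene classes.
#' @param enriched_classes Class indices receiving loaded genes with
#'   probability `enrich_prob`.
#' @param enrich_prob Probability a loaded gene falls in an enriched class.
#' @param seed Integer seed.
#' @return List with `expression` (left regions x genes matrix, gene ids as
#'   column names, region ids as row names) and `genes` (tibble: gene_id,
#'   class, loaded, beta).
#' @export
generate_expression <- function(parcellation, n_genes, target_map,
                                loading_fraction = 0.3, noise_sd = 0.5,
                                n_classes = 7L, enriched_classes = c(1L, 2L),
                                enrich_prob = 0.8, seed = 1L) {
  check_parcellation(parcellation)
  n_genes <- check_count(n_genes, "n_genes")
  check_scalar_number(loading_fraction, "loading_fraction", 0, 1)
  left <- parcellation[parcellation$hemisphere == "L", , drop = FALSE]
  target <- region_values(target_map, left$region_id,
                          what = "target_map (left hemisphere)")
  RL <- nrow(left)
  cent <- parcellation_centroids(left)

  eval_with_seed(seed, {
    n_loaded <- round(loading_fraction * n_genes)
    loaded <- c(rep(TRUE, n_loaded), rep(FALSE, n_genes - n_loaded))
    beta <- ifelse(loaded,
                   sample(c(-1, 1), n_genes, replace = TRUE) *
                     runif(n_genes, 0.5, 1.5),
                   0)
    smooth_noise <- gp_sphere_draw(cent, lengthscale = 0.5, n_draws = n_genes,
                                   nugget = 1e-6)
    E <- matrix(0, RL, n_genes)
    E[, loaded] <- outer(target, beta[loaded]) +
      noise_sd * smooth_noise[, loaded, drop = FALSE]
    E[, !loaded] <- smooth_noise[, !loaded, drop = FALSE]
    E <- apply(E, 2, zscore_pop, what = "gene expression")

    cls <- integer(n_genes)
    other <- setdiff(seq_len(n_classes), enriched_classes)
    for (g in seq_len(n_genes)) {
      cls[g] <- if (loaded[g] && runif(1) < enrich_prob) {
        sample(rep(enriched_classes, 2L), 1L)
      } else {
        sample(rep(if (length(other)) other else seq_len(n_classes), 2L), 1L)
      }
    }
    gene_id <- sprintf("gene_%05d", seq_len(n_genes))
    colnames(E) <- gene_id
    rownames(E) <- left$region_id
    list(expression = E,
         genes = tibble::tibble(gene_id, class = cls, loaded, beta))
  })
}

# Coerce a region map given as a numeric vector or tibble(region_id, value)
# to a numeric vector aligned with `region_ids`.
region_values <- function(map, region_ids, what = "map") {
  if (is.data.frame(map)) {
    if (!all(c("region_id", "value") %in% names(map))) {
      abort(sprintf("%s must have columns region_id and value", what),
            class = "mindgrad_invalid_argument")
    }
    idx <- match(region_ids, map$region_id)
    if (anyNA(idx)) {
      abort(sprintf("%s is missing regions required by the parcellation", what),
            class = "mindgrad_dimension_error")
    }
    out <- map$value[idx]
  } else {
    out <- as.numeric(map)
    if (length(out) != length(region_ids)) {
      abort(sprintf("%s has length %d but %d regions are required",
                    what, length(out), length(region_ids)),
            class = "mindgrad_dimension_error")
    }
  }
  if (!all(is.finite(out))) {
    abort(sprintf("%s contains non-finite values", what),
          class = "mindgrad_invalid_argument")
  }
  out
}
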