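test_that("parcellation geometry, mirroring and determinism hold", {
  parc <- generate_parcellation(20, seed = 3)
  expect_equal(nrow(parc), 40L)
  expect_equal(sum(parc$hemisphere == "L"), 20L)
  norms <- sqrt(parc$x^2 + parc$y^2 + parc$z^2)
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_false(anyDuplicated(parc$region_id) > 0)
  # right hemisphere mirrors left in x
  L <- parc[parc$hemisphere == "L", ]
  R <- parc[parc$hemisphere == "R", ]
  expect_equal(R$x, -L$x)
  expect_equal(R$y, L$y)
  expect_equal(R$z, L$z)
  # labels spatially contiguous sectors: 7 levels each, mirrored
  expect_setequal(unique(parc$network_label), 1:7)
  expect_equal(R$network_label, L$network_label)
  # determinism
  expect_identical(parc, generate_parcellation(20, seed = 3))
  expect_error(generate_parcellation(3), class = "mindgrad_invalid_argument")
})

test_that("cohort generator plants a detectable regional mean shift", {
  parc <- small_parcellation(6)
  # Monte-Carlo over seeds: |t| > 2 on the target region's mean CT
  hits <- vapply(1:25, function(s) {
    co <- generate_cohort(parc, 40, 40, effect_regions = 5L, effect_size = 1,
                          seed = s)
    means <- co$vertices |>
      dplyr::filter(region_id == 5L) |>
      dplyr::group_by(subject_id) |>
      dplyr::summarise(ct = mean(CT), .groups = "drop") |>
      dplyr::left_join(co$covariates, by = "subject_id")
    abs(t.test(ct ~ group, data = means)$statistic) > 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null cohorts have identical case/control law and byte-identical replays", {
  parc <- small_parcellation(5)
  co <- generate_cohort(parc, 4, 4, effect_size = 0, seed = 11)
  expect_identical(co, generate_cohort(parc, 4, 4, effect_size = 0, seed = 11))
  expect_setequal(unique(co$vertices$region_id), parc$region_id)
  expect_false(anyNA(co$vertices))
  # covariate model ranges
  expect_true(all(co$covariates$age >= 21 & co$covariates$age <= 50))
  expect_true(all(co$covariates$sex %in% c(0, 1)))
  expect_true(all(co$covariates$education >= 8))
  expect_error(generate_cohort(parc, 2, 2, effect_regions = 999L),
               class = "mindgrad_invalid_argument")
})

test_that("annotation maps are z-scored with smoothness-controlled autocorrelation", {
  parc <- generate_parcellation(60, seed = 1)
  rough <- generate_annotation_map(parc, smoothness = 0.02, seed = 5)
  smooth <- generate_annotation_map(parc, smoothness = 2, seed = 5)
  for (m in list(rough, smooth)) {
    expect_equal(mean(m$value), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean(m$value^2)), 1, tolerance = 1e-10)
  }
  # Moran-style neighbour correlation within one hemisphere (maps are
  # homotopically mirror-symmetric, so contralateral neighbours on the
  # shared sphere are uninformative): near zero for rough, high for smooth
  left <- which(parc$hemisphere == "L")
  cent <- as.matrix(parc[left, c("x", "y", "z")])
  D <- as.matrix(dist(cent))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  expect_lt(abs(cor(rough$value[left], rough$value[left][nn])), 0.25)
  expect_gt(cor(smooth$value[left], smooth$value[left][nn]), 0.8)
  # homotopic mirror symmetry of whole-brain maps
  expect_gt(cor(smooth$value[parc$hemisphere == "L"],
                smooth$value[parc$hemisphere == "R"]), 0.99)
  expect_error(generate_annotation_map(parc, smoothness = 0),
               class = "mindgrad_invalid_argument")
})

test_that("expression generator respects the left-hemisphere contract and plants loadings", {
  parc <- small_parcellation(20)
  target <- generate_annotation_map(parc, 0.5, seed = 2)
  target_left <- target$value[parc$hemisphere == "L"]
  ex <- generate_expression(parc, 80, target_left, loading_fraction = 0.25,
                            noise_sd = 0.2, seed = 9)
  expect_equal(nrow(ex$expression), sum(parc$hemisphere == "L"))
  expect_equal(ncol(ex$expression), 80L)
  expect_equal(sum(ex$genes$loaded), 20L)
  # per-gene z-scoring
  expect_true(all(abs(colMeans(ex$expression)) < 1e-12))
  expect_true(all(abs(apply(ex$expression, 2, function(c) mean(c^2)) - 1) < 1e-10))
  # loaded genes correlate with the target far beyond background
  r <- abs(cor(ex$expression, target_left))
  expect_gt(min(r[ex$genes$loaded]), max(0.5, median(r[!ex$genes$loaded])))
  expect_error(generate_expression(parc, 10, target$value),
               class = "mindgrad_dimension_error")
  expect_identical(ex, generate_expression(parc, 80, target_left,
                                           loading_fraction = 0.25,
                                           noise_sd = 0.2, seed = 9))
})

test_that("gradient-level cohort simulator plants shifts without disturbing controls", {
  parc <- small_parcellation(10)
  sim <- simulate_gradient_cohort(parc, 30, 30, effect_regions = c(1L, 2L),
                                  effect_size = 1, seed = 4)
  expect_equal(dim(sim$gradient1), c(60L, 20L))
  null_sim <- simulate_gradient_cohort(parc, 30, 30, effect_size = 0, seed = 4)
  grp <- sim$covariates$group
  shift <- colMeans(sim$gradient1[grp == "case", ]) -
    colMeans(sim$gradient1[grp == "control", ])
  expect_true(all(abs(shift[1:2]) > abs(shift[10])))
  # identical RNG stream means non-effect entries agree exactly
  expect_equal(sim$gradient1[, 3:20], null_sim$gradient1[, 3:20])
})
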