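make_gradient_cohort <- function(n_case, n_ctrl, R = 20, effect = NULL,
                                 seed = 1) {
  parc <- generate_parcellation(R / 2, seed = seed)
  simulate_gradient_cohort(parc, n_case, n_ctrl,
                           effect_regions = effect %||% integer(),
                           effect_size = if (is.null(effect)) 0 else 1,
                           seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("region GLM t-values match a normal-equations oracle", {
  sim <- make_gradient_cohort(10, 10, seed = 3)
  res <- fit_region_glm(sim$gradient1, sim$covariates)
  oracle_t <- glm_t_oracle(sim$gradient1, sim$covariates)
  expect_equal(res$t, unname(oracle_t), tolerance = 1e-8)
  expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
  expect_true(all(is.finite(res$t)))
  expect_equal(res$region_id, as.integer(colnames(sim$gradient1)))
})

test_that("degenerate designs are rejected with informative errors", {
  sim <- make_gradient_cohort(8, 8, seed = 4)
  cov1 <- sim$covariates
  cov1$group <- "case"
  expect_error(fit_region_glm(sim$gradient1, cov1),
               class = "mindgrad_design_error")
  cov2 <- sim$covariates
  cov2$education <- cov2$age  # collinear with age
  expect_error(fit_region_glm(sim$gradient1, cov2), regexp = "education|age",
               class = "mindgrad_design_error")
  expect_error(fit_region_glm(sim$gradient1[, 1:5],
                              sim$covariates[1:5, ]),
               class = "mindgrad_dimension_error")
})

test_that("null cohorts give calibrated region-wise p-values", {
  rates <- vapply(1:30, function(s) {
    sim <- make_gradient_cohort(50, 50, R = 40, seed = s)
    mean(fit_region_glm(sim$gradient1, sim$covariates)$p < 0.05)
  }, numeric(1))
  expect_gte(mean(rates), 0.02)
  expect_lte(mean(rates), 0.09)
})

test_that("BH step-up matches the hand oracle and is order invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 6)), rep(1, 6))
  set.seed(2)
  p <- runif(50)^2
  expect_equal(bh_fdr(p), bh_oracle(p))
  o <- sample(50)
  expect_equal(bh_fdr(p[o]), bh_fdr(p)[o])
  expect_error(bh_fdr(c(0.1, -0.2)), class = "mindgrad_invalid_argument")
})

test_that("label aggregation reproduces hand means and finds planted labels", {
  parc <- small_parcellation(4)
  sim <- simulate_gradient_cohort(parc, 12, 12, seed = 5)
  # hand-check label means on a tiny cohort
  labs <- parc$network_label
  agg <- aggregate_by_label(sim$gradient1, sim$covariates, parc, "network")
  expect_equal(nrow(agg), length(unique(labs)))
  one_lab <- unique(labs)[1]
  hand <- rowMeans(sim$gradient1[, labs == one_lab, drop = FALSE])
  refit <- fit_region_glm(cbind(x = hand), sim$covariates)
  expect_equal(agg$t[agg$label == one_lab], refit$t, tolerance = 1e-12)
  # single label equals whole-cortex mean analysis
  parc1 <- parc
  parc1$network_label <- 1L
  agg1 <- aggregate_by_label(sim$gradient1, sim$covariates, parc1, "network")
  whole <- fit_region_glm(cbind(all = rowMeans(sim$gradient1)),
                          sim$covariates)
  expect_equal(agg1$t, whole$t, tolerance = 1e-12)
})

test_that("an effect planted in one label's regions dominates that label", {
  parc <- generate_parcellation(20, seed = 2)
  target_label <- 3L
  eff <- parc$region_id[parc$network_label == target_label]
  hits <- vapply(1:20, function(s) {
    sim <- simulate_gradient_cohort(parc, 25, 25, effect_regions = eff,
                                    effect_size = 1, seed = s)
    agg <- aggregate_by_label(sim$gradient1, sim$covariates, parc, "network")
    agg$label[which.max(abs(agg$t))] == target_label
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("KS distribution test matches the brute-force ECDF gap", {
  set.seed(9)
  a <- rnorm(40)
  b <- rnorm(40, 0.5)
  res <- distribution_test(a, b)
  expect_equal(res$statistic, ks_stat_oracle(a, b), tolerance = 1e-12)
  same <- distribution_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  far <- distribution_test(rnorm(50), rnorm(50, 3))
  expect_lt(far$p, 0.001)
  expect_error(distribution_test(a[1:3], b),
               class = "mindgrad_insufficient_sample")
})

test_that("t-map vs reference map uses the spin machinery", {
  parc <- small_parcellation(17)
  ens <- build_spin_ensemble(parc, 99, seed = 4)
  m <- generate_annotation_map(parc, 0.5, seed = 6)
  res <- tmap_vs_reference(m$value, m, ens)
  expect_equal(res$r, 1)
  expect_lte(res$p_spin, 0.05)
})

test_that("nuisance covariates and subsampling leave the t-map stable", {
  parc <- generate_parcellation(20, seed = 7)
  eff <- parc$region_id[1:4]
  sim <- simulate_gradient_cohort(parc, 20, 60, effect_regions = eff,
                                  effect_size = 1, seed = 7)
  full <- fit_region_glm(sim$gradient1, sim$covariates)
  # adding a nuisance covariate uncorrelated with group barely moves t
  set.seed(1)
  tiv <- rnorm(nrow(sim$covariates))
  # emulate the TIV check by residualizing g1 on the nuisance first
  g_res <- apply(sim$gradient1, 2, function(g) resid(lm(g ~ tiv)))
  alt <- fit_region_glm(g_res, sim$covariates)
  expect_lt(median(abs(alt$t - full$t)), 0.2)
  # size-matched control subsample keeps the spatial pattern
  keep <- c(which(sim$covariates$group == "case"),
            sample(which(sim$covariates$group == "control"), 20))
  subs <- fit_region_glm(sim$gradient1[keep, ], sim$covariates[keep, ])
  expect_gt(cor(subs$t, full$t), 0.5)
})
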