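test_that("PLS captures exact and null relationships", {
  set.seed(1)
  y <- rnorm(30)
  X1 <- cbind(a = y)
  fit <- fit_pls(X1, y, n_components = 1)
  expect_equal(fit$variance_explained_y[1], 1, tolerance = 1e-12)
  # response orthogonal to all predictors explains nothing
  Q <- qr.Q(qr(cbind(1, rnorm(30), rnorm(30), rnorm(30))))
  Xo <- Q[, 2:3]
  colnames(Xo) <- c("p1", "p2")
  yo <- Q[, 4]
  fit0 <- fit_pls(Xo, yo, n_components = 2)
  expect_lt(fit0$variance_explained_y[1], 1e-20)
  expect_error(fit_pls(Xo, rep(2, 30), 2),
               class = "mindgrad_degenerate_response")
})

test_that("one-component fit matches an independent NIPALS oracle", {
  set.seed(6)
  X <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(6)
  fit <- fit_pls(X, y, n_components = 2)
  # fitted response from component 1: score * loading
  t1 <- fit$region_scores[, 1]
  fitted1 <- t1 * sum(t1 * (y - mean(y))) / sum(t1^2)
  expect_equal(fitted1, nipals_fitted1(X, y), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PLS orientation and sign invariances hold", {
  parc <- small_parcellation(17)
  t_map <- generate_annotation_map(parc, 0.5, seed = 3)$value
  ex <- generate_expression(parc, 60, t_map[parc$hemisphere == "L"],
                            loading_fraction = 0.4, seed = 4)
  yl <- t_map[parc$hemisphere == "L"]
  fit <- fit_pls(ex$expression, yl, n_components = 5)
  # orientation: PLS1 scores correlate nonnegatively with the response
  expect_gte(cor(fit$region_scores[, 1], yl), 0)
  # component-1 dominance
  expect_true(all(fit$variance_explained_y[1] >=
                    fit$variance_explained_y[-1]))
  # flipping y flips weights/scores, preserves variance explained
  fit_neg <- fit_pls(ex$expression, -yl, n_components = 5)
  expect_equal(fit_neg$variance_explained_y, fit$variance_explained_y,
               tolerance = 1e-9)
  expect_equal(abs(cor(fit_neg$weights[, 1], fit$weights[, 1])), 1,
               tolerance = 1e-9)
})

test_that("spin significance of PLS1 is extreme for real structure, calibrated under null", {
  parc <- small_parcellation(17)
  ens <- build_spin_ensemble(parc, 199, seed = 5)
  left_ids <- parc$region_id[parc$hemisphere == "L"]
  ens_l <- subset_spin_ensemble(ens, left_ids)
  target <- generate_annotation_map(parc, 0.5, seed = 6)$value
  yl <- target[parc$hemisphere == "L"]
  ex <- generate_expression(parc, 80, yl, loading_fraction = 0.4,
                            noise_sd = 0.2, seed = 7)
  strong <- spin_significance_of_component(ex$expression, yl, ens_l, 5)
  expect_lte(strong$p_spin, 0.05)
  expect_identical(strong,
                   spin_significance_of_component(ex$expression, yl, ens_l, 5))
  # unrelated response: p should not be extreme
  y0 <- generate_annotation_map(parc, 0.5, seed = 999)$value[
    parc$hemisphere == "L"]
  ex0 <- generate_expression(parc, 80, yl, loading_fraction = 0, seed = 8)
  null_p <- spin_significance_of_component(ex0$expression, y0, ens_l, 5)
  expect_gt(null_p$p_spin, 0.01)
})

test_that("bootstrap Z-scores obey symmetry and sign contracts and recover loadings", {
  parc <- small_parcellation(17)
  target <- generate_annotation_map(parc, 0.5, seed = 10)$value
  yl <- target[parc$hemisphere == "L"]
  ex <- generate_expression(parc, 60, yl, loading_fraction = 0.3,
                            noise_sd = 0.3, seed = 11)
  X <- ex$expression
  # duplicate a predictor column: duplicated columns get near-equal Z
  X2 <- cbind(X, dup = X[, 1])
  bz <- bootstrap_weight_z(X2, yl, n_components = 5, n_boot = 400, seed = 12)
  z_orig <- bz$z[1]
  z_dup <- bz$z[ncol(X2)]
  expect_lt(abs(z_orig - z_dup), 0.3)
  # sign contract for retained predictors
  kept <- bz[bz$significant, ]
  expect_true(all(sign(kept$z) == sign(kept$weight)))
  # planted genes dominate the significant set
  bz1 <- bootstrap_weight_z(X, yl, n_components = 5, n_boot = 400, seed = 13)
  loaded <- ex$genes$loaded
  recall <- mean(bz1$significant[loaded])
  expect_gte(recall, 0.8)
  expect_gt(mean(abs(bz1$z[loaded])), mean(abs(bz1$z[!loaded])))
})

test_that("score-target correlation is near 1 for noiseless constructions", {
  parc <- small_parcellation(17)
  ens <- build_spin_ensemble(parc, 99, seed = 14)
  ens_l <- subset_spin_ensemble(ens, parc$region_id[parc$hemisphere == "L"])
  target <- generate_annotation_map(parc, 0.5, seed = 15)$value
  yl <- target[parc$hemisphere == "L"]
  ex <- generate_expression(parc, 50, yl, loading_fraction = 1,
                            noise_sd = 1e-3, seed = 16)
  fit <- fit_pls(ex$expression, yl, n_components = 3)
  res <- score_target_correlation(fit, yl, ens_l)
  expect_gt(res$r, 0.99)
  expect_lte(res$p_spin, 0.05)
})

test_that("decode_pls bundles fit, spin and bootstrap with tidy access", {
  parc <- small_parcellation(17)
  ens <- build_spin_ensemble(parc, 99, seed = 17)
  ens_l <- subset_spin_ensemble(ens, parc$region_id[parc$hemisphere == "L"])
  target <- generate_annotation_map(parc, 0.5, seed = 18)$value
  yl <- target[parc$hemisphere == "L"]
  ex <- generate_expression(parc, 40, yl, seed = 19)
  res <- decode_pls(ex$expression, yl, ens_l, n_components = 4,
                    n_boot = 150, seed = 20)
  expect_false(is.na(res$p_spin_component1))
  expect_equal(nrow(res$predictors), 40L)
  expect_setequal(unique(res$predictors$direction), c("positive", "negative"))
  expect_equal(nrow(tidy(res)), 40L)
  expect_s3_class(autoplot(res), "ggplot")
  gl <- glance(res)
  expect_equal(gl$n_predictors, 40L)
})
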