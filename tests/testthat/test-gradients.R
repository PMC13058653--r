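test_that("row thresholding keeps the right entries with deterministic ties", {
  set.seed(2)
  R <- 11
  M <- matrix(runif(R * R), R, R)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  thr <- threshold_rows(M, 0.1)  # ceil(0.1 * 10) = 1 entry per row
  expect_true(all(rowSums(thr > 0) == 1))
  expect_equal(apply(thr, 1, max), apply(M - diag(diag(M)), 1, max))
  # fraction 1 keeps everything off-diagonal
  expect_equal(threshold_rows(M, 1), M - diag(diag(M)))
  # ties at the cutoff go to the lower region index
  Tie <- matrix(0.5, 4, 4)
  diag(Tie) <- 0
  thr_tie <- threshold_rows(Tie, 0.3)  # keeps 1 of 3 equal entries
  expect_equal(which(thr_tie[1, ] > 0), 2L)
  expect_equal(which(thr_tie[2, ] > 0), 1L)
  expect_error(threshold_rows(M, 0), class = "mindgrad_invalid_argument")
})

test_that("normalized-angle affinity matches closed-form angles", {
  M <- rbind(c(1, 0), c(1, 1))
  A <- normalized_angle_affinity(M)
  expect_equal(A[1, 2], 0.75, tolerance = 1e-12)  # 1 - (pi/4)/pi
  expect_equal(diag(A), c(1, 1))
  # orthogonal nonnegative rows -> 0.5; identical rows -> 1
  B <- normalized_angle_affinity(rbind(c(1, 0), c(0, 2), c(3, 0)))
  expect_equal(B[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(B[1, 3], 1, tolerance = 1e-12)
  # bounds for nonnegative rows on simulated thresholded matrices
  set.seed(5)
  W <- threshold_rows(abs(matrix(rnorm(900), 30, 30)), 0.2)
  A2 <- normalized_angle_affinity(W)
  expect_true(all(A2 >= 0.5 - 1e-12 & A2 <= 1 + 1e-12))
  expect_lt(max(abs(A2 - t(A2))), 1e-12)
  expect_error(normalized_angle_affinity(rbind(c(0, 0), c(1, 1))),
               class = "mindgrad_degenerate_region")
})

test_that("diffusion embedding matches a dense eigensolver on a ring graph", {
  R <- 40
  W <- matrix(0, R, R)
  idx <- cbind(seq_len(R), c(2:R, 1))
  W[idx] <- 1; W[idx[, 2:1]] <- 1
  W[cbind(seq_len(R), c(3:R, 1, 2))] <- 0.4
  W <- pmax(W, t(W))
  gs <- diffusion_embed(W, alpha = 0.5, n_components = 5)
  # oracle: explicit Markov operator eigendecomposition
  d <- rowSums(W)
  Wa <- W / outer(d^0.5, d^0.5)
  P <- Wa / rowSums(Wa)
  ev <- sort(Re(eigen(P)$values), decreasing = TRUE)
  lam <- ev[2:6]
  expect_equal(gs$lambdas, lam, tolerance = 1e-8)
  expect_equal(gs$variance_explained, lam / sum(lam), tolerance = 1e-8)
  expect_equal(sum(gs$variance_explained), 1, tolerance = 1e-12)
  # first gradient is a sinusoid in node index (within the degenerate pair)
  i <- seq_len(R)
  fit <- lm(gs$components[, 1] ~ cos(2 * pi * i / R) + sin(2 * pi * i / R))
  expect_gt(abs(cor(fitted(fit), gs$components[, 1])), 0.99)
})

test_that("two-block affinity separates blocks in gradient 1 and errors propagate", {
  B <- matrix(0.05, 20, 20)
  B[1:10, 1:10] <- 0.9
  B[11:20, 11:20] <- 0.9
  diag(B) <- 1
  gs <- diffusion_embed(B, n_components = 3)
  g1 <- gs$components[, 1]
  expect_true(all(sign(g1[1:10]) == sign(g1[1])))
  expect_true(all(sign(g1[11:20]) == -sign(g1[1])))
  expect_error(diffusion_embed(matrix(c(0, 1, 0, 1), 2), n_components = 1),
               class = "mindgrad_invalid_argument")
  disc <- diag(2)
  expect_error(diffusion_embed(cbind(rbind(disc, 0 * disc),
                                     rbind(0 * disc, disc)),
                               n_components = 1),
               class = "mindgrad_connectivity_error")
})

test_that("group template equals individual embedding for identical subjects", {
  parc <- small_parcellation(6)
  co <- generate_cohort(parc, 1, 1, seed = 8)
  minds <- build_cohort_mind(co$vertices, parc)
  same <- list(a = minds[[1]], b = minds[[1]], c = minds[[1]])
  tmpl <- build_group_template(same, n_components = 4)
  ind <- embed_mind(minds[[1]], n_components = 4)
  for (j in 1:4) {
    expect_equal(abs(cor(tmpl$components[, j], ind$components[, j])), 1,
                 tolerance = 1e-6)
  }
  expect_identical(tmpl, build_group_template(same, n_components = 4))
  # anchor-set orientation: gradient 1 mean over top-degree decile positive
  mean_mat <- minds[[1]]$values
  deg <- rowSums(mean_mat) / (nrow(mean_mat) - 1)
  anchors <- order(deg, decreasing = TRUE)[1]
  expect_gte(mean(tmpl$components[anchors, 1]), 0)
})

test_that("Procrustes alignment recovers rotations and reflections", {
  parc <- small_parcellation(8)
  co <- generate_cohort(parc, 2, 2, seed = 13)
  minds <- build_cohort_mind(co$vertices, parc)
  tmpl <- build_group_template(minds, n_components = 5)
  expect_equal(procrustes_align(tmpl, tmpl)$components, tmpl$components,
               tolerance = 1e-9)
  # sign flip of gradient 1 is undone
  flipped <- tmpl
  flipped$components[, 1] <- -flipped$components[, 1]
  re <- procrustes_align(flipped, tmpl)
  expect_gt(cor(re$components[, 1], tmpl$components[, 1]), 0.999)
  # random orthogonal rotation recovered within 1e-6 Frobenius
  set.seed(99)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  rotated <- tmpl
  rotated$components <- tmpl$components %*% Q
  back <- procrustes_align(rotated, tmpl)
  expect_lt(sqrt(sum((back$components - tmpl$components)^2)), 1e-6)
})

test_that("cohort gradients are aligned, oriented, and expose tidy access", {
  parc <- small_parcellation(6)
  co <- generate_cohort(parc, 3, 3, seed = 17)
  minds <- build_cohort_mind(co$vertices, parc)
  fit <- fit_cohort_gradients(minds, n_components = 4)
  expect_equal(dim(fit$gradient1), c(6L, 12L))
  expect_true(all(diff(fit$template$lambdas) <= 1e-12))
  expect_true(all(diff(fit$template$variance_explained) <= 1e-12))
  # aligned individuals correlate with the template's principal gradient
  cors <- vapply(fit$individuals, function(g) {
    cor(g$components[, 1], fit$template$components[, 1])
  }, numeric(1))
  expect_true(all(cors > 0))
  td <- tidy(fit$template)
  expect_equal(nrow(td), 12L * 4L)
  expect_s3_class(autoplot(fit$template), "ggplot")
  expect_equal(glance(fit$template)$n_components, 4L)
})
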