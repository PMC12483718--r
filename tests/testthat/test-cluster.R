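test_that("CFE recovers well-separated planted clusters exactly", {
  demo <- generate_clustered_demo(n = 90, r = 2, k = 3, separation = 6,
                                  noise_half_width = 0.25, seed = 7)
  cfe <- fit_cfe(demo$data, r = 2, k = 3,
                 control = fe_control(alpha = 0.01, n_starts = 10, seed = 3))
  expect_equal(cluster_agreement(cfe$cluster, demo$cluster), 1)
  expect_true(all(rowSums(cfe$membership) == 1))
  expect_true(all(cfe$membership %in% c(0, 1)))
  expect_true(all(diff(cfe$loss_path) <= 1e-9))
  expect_lt(check_constraint(cfe$scores)$max_deviation, 1e-6)
})

test_that("CFE and CCFE memberships coincide on strongly clustered data", {
  demo <- generate_clustered_demo(n = 90, r = 2, k = 3, separation = 6,
                                  noise_half_width = 0.25, seed = 7)
  cfe <- fit_cfe(demo$data, r = 2, k = 3,
                 control = fe_control(alpha = 0.01, n_starts = 10, seed = 3))
  ccfe <- fit_ccfe(demo$data, r = 2, k = 3, control = fe_control(n_starts = 10, seed = 3))
  expect_equal(cluster_agreement(cfe$cluster, ccfe$cluster), 1)
  # and the matched score columns correlate near-perfectly
  al <- procrustes_align(ccfe$scores$F, cfe$scores$F)$aligned
  expect_true(all(score_correlations(al, cfe$scores$F) > 0.95))
})

test_that("CFE with a vanishing penalty matches plain MDFA parameters", {
  demo <- generate_nocluster_demo(n = 120, seed = 8)
  cfe <- fit_cfe(demo$data, r = 2, k = 3,
                 control = fe_control(alpha = 1e-6, n_starts = 5, seed = 4))
  md <- fit_mdfa(demo$data, r = 2, control = fe_control(n_starts = 5, seed = 4))
  al <- procrustes_align(cfe$params$A, md$params$A)$aligned
  expect_lt(rmsea(al, md$params$A), 1e-3)
  expect_lt(rmsea(cfe$params$psi, md$params$psi), 1e-3)
})

test_that("single-cluster CFE centers the penalty on the score mean", {
  demo <- generate_nocluster_demo(n = 80, seed = 9)
  cfe <- fit_cfe(demo$data, r = 2, k = 1,
                 control = fe_control(alpha = 0.01, n_starts = 3, seed = 2))
  expect_equal(dim(cfe$centroids), c(1L, 2L))
  expect_equal(cfe$centroids[1, ], colMeans(cfe$scores$F), tolerance = 1e-8)
})

test_that("CCFE stage two is monotone and preserves the constraint", {
  demo <- generate_nocluster_demo(n = 100, seed = 10)
  ccfe <- fit_ccfe(demo$data, r = 2, k = 3, control = fe_control(n_starts = 5, seed = 6))
  expect_true(all(diff(ccfe$stage2_path) <= 1e-9))
  expect_lt(check_constraint(ccfe$scores)$max_deviation, 1e-6)
  # stage 2 must not change the factor-model fit itself (up to the final
  # parameter refresh of stage 1, whose scores are re-derived in stage 2)
  expect_equal(mdfa_loss(ccfe$data, ccfe$params, ccfe$scores), ccfe$best_loss,
               tolerance = 1e-4)
})

test_that("CCFE carves sharper clusters than CFE on cluster-free data", {
  demo <- generate_nocluster_demo(n = 200, seed = 11)
  cfe <- fit_cfe(demo$data, r = 2, k = 3,
                 control = fe_control(alpha = 0.01, n_starts = 10, seed = 5))
  ccfe <- fit_ccfe(demo$data, r = 2, k = 3, control = fe_control(n_starts = 10, seed = 5))
  expect_gt(cluster_stats(cfe)$min_within, cluster_stats(ccfe)$min_within)
})

test_that("cluster statistics match a double-loop computation", {
  # members at their centroid -> zero within variance
  F0 <- rbind(matrix(1, 4, 2), matrix(-1, 4, 2))
  st0 <- cluster_stats(F0, rep(1:2, each = 4))
  expect_equal(st0$within$within_variance, c(0, 0))

  # 3-4-5 triangle distance
  st1 <- cluster_stats(rbind(c(0, 0), c(3, 4)), 1:2)
  expect_equal(st1$max_between, 5)

  set.seed(61)
  F <- matrix(rnorm(60), 20, 3)
  cl <- sample(1:3, 20, replace = TRUE)
  while (length(unique(cl)) < 3) cl <- sample(1:3, 20, replace = TRUE)
  st <- cluster_stats(F, cl)
  for (g in 1:3) {
    idx <- which(cl == g)
    cen <- colMeans(F[idx, , drop = FALSE])
    acc <- 0
    for (i in idx) acc <- acc + sum((F[i, ] - cen)^2)
    expect_equal(st$within$within_variance[g], acc / length(idx), tolerance = 1e-12)
  }
  expect_error(cluster_stats(F, c(rep(1, 19), 3)), "Empty cluster")
})
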