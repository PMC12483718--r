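test_that("rmsea matches its definition", {
  M <- matrix(rnorm(12), 4, 3)
  expect_equal(rmsea(M, M), 0)
  expect_equal(rmsea(matrix(0.1, 2, 2), matrix(0, 2, 2)), 0.1)
  set.seed(81)
  A <- matrix(rnorm(20), 5, 4); B <- matrix(rnorm(20), 5, 4)
  acc <- 0
  for (i in 1:5) for (j in 1:4) acc <- acc + (A[i, j] - B[i, j])^2
  expect_equal(rmsea(A, B), sqrt(acc / 20), tolerance = 1e-14)
  expect_error(rmsea(A, B[, 1:3]), "identical dimensions")
})

test_that("local solution proportion counts relative excess over the best start", {
  expect_equal(local_solution_proportion(rep(2.5, 6)), 0)
  expect_equal(local_solution_proportion(c(1, 1, 2), threshold = 1e-4), 1 / 3)
  expect_equal(local_solution_proportion(c(1, 1 + 1e-6, 1 + 5e-5), threshold = 1e-4), 0)
  expect_error(local_solution_proportion(numeric(0)), "empty")
})

test_that("Bartlett scores solve the row-wise generalized least squares problem", {
  # plug-in: exact model, unit uniqueness, loadings with orthogonal columns
  set.seed(82)
  F0 <- matrix(rnorm(60), 30, 2)
  A <- rbind(matrix(c(0.9, 0), 3, 2, byrow = TRUE),
             matrix(c(0, 0.8), 3, 2, byrow = TRUE))
  X <- tcrossprod(F0, A)
  expect_equal(bartlett_scores(X, A, rep(1, 6)), F0, tolerance = 1e-10)
  # linear in the data
  expect_equal(bartlett_scores(2 * X, A, rep(1, 6)),
               2 * bartlett_scores(X, A, rep(1, 6)))

  # row-wise GLS oracle with heteroscedastic uniqueness
  psi <- runif(6, 0.4, 1.2)
  Xn <- X + matrix(rnorm(180, sd = 0.3), 30, 6)
  S <- bartlett_scores(Xn, A, psi)
  for (i in c(1, 7, 30)) {
    W <- diag(1 / psi^2)
    f_i <- solve(t(A) %*% W %*% A, t(A) %*% W %*% Xn[i, ])
    expect_equal(S[i, ], as.numeric(f_i), tolerance = 1e-10)
  }
  expect_error(bartlett_scores(Xn, A, c(psi[-6], 1e-12)), "Near-zero uniqueness")
})

test_that("score correlations match the textbook formula", {
  set.seed(83)
  F1 <- matrix(rnorm(40), 20, 2)
  expect_equal(score_correlations(F1, F1), c(1, 1))
  expect_equal(score_correlations(F1, -F1), c(-1, -1))
  F2 <- F1 + matrix(rnorm(40, sd = 0.5), 20, 2)
  longhand <- vapply(1:2, function(j) {
    x <- F1[, j]; y <- F2[, j]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }, numeric(1))
  expect_equal(score_correlations(F1, F2), longhand, tolerance = 1e-12)
  expect_error(score_correlations(cbind(F1[, 1], 0), F2), "Zero-variance")
})

test_that("Cohen's d and its interval match a long-hand computation", {
  g1 <- c(2.1, 1.9, 2.5, 2.2, 2.0)
  g2 <- c(1.2, 1.5, 1.1, 1.6)
  out <- cohens_d_ci(g1, g2)
  sp <- sqrt((4 * var(g1) + 3 * var(g2)) / 7)
  d <- (mean(g1) - mean(g2)) / sp
  se <- sqrt(9 / 20 + d^2 / 18)
  expect_equal(out$d, d, tolerance = 1e-12)
  expect_equal(out$lower, d - qnorm(0.975) * se, tolerance = 1e-12)
  expect_equal(out$upper, d + qnorm(0.975) * se, tolerance = 1e-12)
  expect_equal(cohens_d_ci(g1, g1)$d, 0)
  expect_error(cohens_d_ci(rep(1, 5), rep(1, 4)), "Zero pooled")
})

test_that("individual residuals decompose the factor loss and expose outliers", {
  sim <- generate_dataset(simulation_design(n = 80, p = 6, q = 2, r = 2,
                                            rho = 1, seed = 84))
  fit <- fit_rfe(sim$data, 2, control = fe_control(n_starts = 5, seed = 2, tol = 1e-13))
  res <- individual_residuals(fit)
  expect_true(all(res$residual < 1e-4))

  # corrupt one row: it must dominate the residuals
  Xc <- sim$data$X
  Xc[17, ] <- Xc[17, ] + 4
  dc <- fe_data(Xc, sim$data$Y, center = TRUE)
  fitc <- fit_rfe(dc, 2, control = fe_control(n_starts = 5, seed = 2))
  resc <- individual_residuals(fitc)
  expect_equal(which.max(resc$residual), 17L)
  # squared row norms sum to the factor part of the loss
  expect_equal(sum(resc$residual^2),
               mdfa_loss(fitc$data, fitc$params, fitc$scores), tolerance = 1e-10)
})
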