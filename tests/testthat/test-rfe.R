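test_that("block stacking reproduces the objective as one Frobenius norm", {
  inst <- make_exact_instance(n = 20, p = 4, r = 2, q = 2, seed = 41)
  set.seed(42)
  pr <- fe_params(matrix(rnorm(8), 4, 2), runif(4), B = matrix(rnorm(4), 2, 2))
  a <- 0.37
  bl <- build_blocks(inst$data, pr, a)
  Z <- cbind(inst$scores$F, inst$scores$U)
  expect_equal(sum((bl$G - Z %*% t(bl$W))^2),
               rfe_loss(inst$data, pr, inst$scores, a), tolerance = 1e-12)

  # without criteria the blocks reduce to X and [A, Psi]
  d0 <- fe_data(inst$data$X, center = FALSE)
  pr0 <- fe_params(pr$A, pr$psi)
  bl0 <- build_blocks(d0, pr0, 1)
  expect_identical(bl0$G, inst$data$X)
  expect_equal(bl0$W, cbind(pr$A, diag(pr$psi, 4)))

  # B = 0 zeroes the criterion rows of the weight block
  prB0 <- fe_params(pr$A, pr$psi, B = matrix(0, 2, 2))
  blB0 <- build_blocks(inst$data, prB0, a)
  expect_true(all(blB0$W[5:6, ] == 0))
  expect_error(build_blocks(inst$data, pr, 0), "positive")
})

test_that("score update satisfies the constraint and maximizes the trace objective", {
  set.seed(43)
  n <- 8; p <- 3; q <- 2; r <- 2
  X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Y <- scale(matrix(rnorm(n * q), n, q), scale = FALSE)
  d <- fe_data(X, Y, center = FALSE)
  pr <- fe_params(matrix(rnorm(p * r), p, r), runif(p, 0.2, 1),
                  B = matrix(rnorm(q * r), q, r))
  bl <- build_blocks(d, pr, 0.5)
  sc <- update_scores(bl, n)
  Z <- cbind(sc$F, sc$U)
  expect_lt(max(abs(crossprod(Z) / n - diag(r + p))), 1e-10)

  # random-search oracle: no random constrained Z beats the update
  GW <- bl$G %*% bl$W
  obj <- sum(GW * Z)
  set.seed(44)
  for (i in 1:1000) {
    Zr <- sqrt(n) * qr.Q(qr(matrix(rnorm(n * (r + p)), n)))
    expect_lte(sum(GW * Zr), obj + 1e-8)
  }
})

test_that("score update attains zero loss when the weights are the generating ones", {
  inst <- make_exact_instance(n = 30, p = 4, r = 2, q = 2, seed = 45)
  bl <- build_blocks(inst$data, inst$params, 1)
  sc <- update_scores(bl, 30)
  expect_lt(sum((bl$G - cbind(sc$F, sc$U) %*% t(bl$W))^2), 1e-16)
})

test_that("psi update is the constrained scalar least squares minimizer", {
  inst <- make_exact_instance(n = 40, p = 5, r = 2, q = 0, seed = 46)
  d <- inst$data; sc <- inst$scores

  # plug-in: X built with psi0 recovers psi0 exactly... after removing the
  # common part contribution (F'U = 0 makes it drop out)
  expect_equal(update_psi(d, sc), inst$params$psi, tolerance = 1e-10,
               ignore_attr = TRUE)

  # U orthogonal to X -> psi = 0: swap in fresh orthonormal directions
  perp <- qr.Q(qr(cbind(d$X, sc$F, matrix(rnorm(40 * 5), 40))))[, 8:12]
  sc_perp <- fe_scores(sc$F, sqrt(40) * perp)
  expect_equal(update_psi(d, sc_perp), rep(0, 5), ignore_attr = TRUE)

  # 1-D grid oracle per coordinate: the update beats every grid candidate
  set.seed(47)
  A_it <- matrix(rnorm(10), 5, 2)
  psi_hat <- update_psi(d, sc)
  for (j in 1:5) {
    resid_j <- d$X[, j] - sc$F %*% A_it[j, ]
    grid <- seq(-1.5, 1.5, by = 0.002)
    sse <- vapply(grid, function(ps) sum((resid_j - ps * sc$U[, j])^2), numeric(1))
    expect_lt(abs(grid[which.min(sse)] - psi_hat[j]), 2e-3)
  }
})

test_that("coefficient update solves the normal equations given orthonormal scores", {
  inst <- make_exact_instance(n = 30, p = 4, r = 2, q = 2, seed = 48)
  cf <- update_coefficients(inst$data, inst$scores)
  expect_equal(cf$A, inst$params$A, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(cf$B, inst$params$B, tolerance = 1e-10, ignore_attr = TRUE)

  # explicit normal-equation oracle on a noisy instance
  set.seed(49)
  Xn <- inst$data$X + matrix(rnorm(120, sd = 0.3), 30, 4)
  Xn <- scale(Xn, scale = FALSE)
  dn <- fe_data(Xn, inst$data$Y, center = FALSE)
  cfn <- update_coefficients(dn, inst$scores)
  F <- inst$scores$F
  A_ne <- t(solve(crossprod(F), crossprod(F, Xn)))
  expect_equal(cfn$A, A_ne, tolerance = 1e-10, ignore_attr = TRUE)

  # criteria orthogonal to the scores give B = 0
  Yp <- qr.resid(qr(F), inst$data$Y)
  dp <- fe_data(inst$data$X, scale(Yp, scale = FALSE), center = FALSE)
  expect_lt(max(abs(update_coefficients(dp, inst$scores)$B)), 1e-10)
})

test_that("RFE recovers a noise-free model to machine-level loss", {
  sim <- generate_dataset(simulation_design(n = 120, p = 8, q = 3, r = 2,
                                            rho = 1, seed = 50))
  fit <- fit_rfe(sim$data, 2,
                 control = fe_control(n_starts = 8, seed = 5, tol = 1e-13))
  expect_lt(fit$best_loss, 1e-8)
  rep <- recovery_report(fit, sim$truth)
  expect_lt(rep$rmsea_A, 1e-4)
  expect_lt(rep$rmsea_B, 1e-4)
  expect_lt(rep$rmsea_uniqueness, 1e-4)
})

test_that("identified fits give the same scores from independent starts", {
  sim <- generate_dataset(simulation_design(n = 100, p = 6, q = 3, r = 2,
                                            rho = 0.9, seed = 51))
  ctrl <- function(seed) fe_control(alpha = 0.5, n_starts = 5, seed = seed,
                                    tol = 1e-15, max_iter = 5000)
  f1 <- fit_rfe(sim$data, 2, control = ctrl(11))
  f2 <- fit_rfe(sim$data, 2, control = ctrl(912))
  al <- procrustes_align(f1$scores$F, f2$scores$F)
  expect_lt(max(abs(al$aligned - f2$scores$F)), 1e-6)
})

test_that("RFE with a vanishing penalty agrees with plain MDFA", {
  sim <- generate_dataset(simulation_design(n = 100, p = 6, q = 2, r = 2,
                                            rho = 0.9, seed = 52))
  rf <- fit_rfe(sim$data, 2, control = fe_control(alpha = 1e-6, n_starts = 5, seed = 3))
  md <- fit_mdfa(sim$data, 2, control = fe_control(n_starts = 5, seed = 3))
  al <- procrustes_align(rf$params$A, md$params$A)$aligned
  expect_lt(rmsea(al, md$params$A), 1e-3)
})

test_that("RFE validates its inputs and warns on under-identification", {
  sim <- generate_dataset(simulation_design(n = 60, p = 5, q = 1, r = 2,
                                            rho = 0.9, seed = 53))
  expect_warning(fit_rfe(sim$data, 2, control = fe_control(n_starts = 2, seed = 1)),
                 "not guaranteed")
  d0 <- fe_data(sim$data$X, center = FALSE)
  expect_error(fit_rfe(d0, 2), "external criteria")
  expect_error(fit_rfe(sim$data, 5), "smaller than")
})

test_that("identification report flags Theorem-style conditions", {
  sim <- generate_dataset(simulation_design(n = 100, p = 6, q = 2, r = 2,
                                            rho = 0.9, seed = 54))
  fit <- fit_rfe(sim$data, 2, control = fe_control(n_starts = 5, seed = 2))
  rep <- check_identification(fit)
  expect_true(all(rep$ok))
  # scores live in the column space of the observed variables and criteria
  expect_lt(rep$value[rep$condition == "F lies in the column space of [X, Y] (relative residual)"],
            1e-8)

  # plain MDFA is reported as not uniquely determined
  md <- fit_mdfa(fe_data(sim$data$X, center = FALSE), 2,
                 control = fe_control(n_starts = 3, seed = 2))
  expect_false(all(check_identification(md)$ok))

  # duplicated criterion column -> B rank deficiency flagged
  Ydup <- cbind(sim$data$Y[, 1], sim$data$Y[, 1])
  ddup <- fe_data(sim$data$X, Ydup, center = FALSE)
  fdup <- suppressWarnings(fit_rfe(ddup, 2, control = fe_control(n_starts = 3, seed = 2)))
  rdup <- check_identification(fdup)
  expect_false(rdup$ok[rdup$condition == "B has full column rank"])
})
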