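test_that("fe_data validates, centers, and drops incomplete rows", {
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
  d <- fe_data(X)
  expect_s3_class(d, "fe_data")
  expect_lt(max(abs(colMeans(d$X))), 1e-12)

  Xna <- X
  Xna[3, 2] <- NA
  expect_message(d2 <- fe_data(Xna), "Dropped 1 row")
  expect_equal(nrow(d2$X), 9)

  # estimators refuse silently-uncentered input
  expect_error(fit_mdfa(X + 5, r = 2), "not centered")
  expect_error(fe_data(X, y = matrix(1, 3, 1)), "rows")
})

test_that("constraint check accepts orthonormal constructions and flags violations", {
  n <- 12
  Z <- sqrt(n) * qr.Q(qr(matrix(rnorm(n * n), n)))[, 1:6]
  s <- fe_scores(Z[, 1:2], Z[, 3:6])
  chk <- check_constraint(s)
  expect_true(chk$ok)
  expect_lt(chk$max_deviation, 1e-12)

  # scaling a block breaks the diagonal
  expect_false(check_constraint(fe_scores(2 * s$F, s$U))$ok)
  # duplicating a column across blocks puts a 1 off the diagonal
  s_dup <- fe_scores(cbind(s$F[, 1], s$U[, 1]), s$U)
  expect_false(check_constraint(s_dup)$ok)
  expect_error(fe_scores(s$F[1:5, ], s$U), "rows")
})

test_that("mdfa_loss matches the brute-force residual sum", {
  inst <- make_exact_instance(n = 25, p = 4, r = 2, q = 0, seed = 3)
  expect_lt(mdfa_loss(inst$data, inst$params, inst$scores), 1e-20)

  zero <- fe_params(matrix(0, 4, 2), rep(0, 4))
  expect_equal(mdfa_loss(inst$data, zero, inst$scores), sum(inst$data$X^2))

  set.seed(9)
  pr <- fe_params(matrix(rnorm(8), 4, 2), runif(4))
  expect_equal(mdfa_loss(inst$data, pr, inst$scores),
               loop_mdfa_loss(inst$data$X, pr$A, pr$psi,
                              inst$scores$F, inst$scores$U),
               tolerance = 1e-12)
})

test_that("rfe_loss is the mdfa term plus alpha times the regression term", {
  inst <- make_exact_instance(n = 25, p = 4, r = 2, q = 2, seed = 4)
  expect_lt(rfe_loss(inst$data, inst$params, inst$scores, alpha = 0.3), 1e-18)

  set.seed(10)
  pr <- fe_params(matrix(rnorm(8), 4, 2), runif(4), B = matrix(rnorm(4), 2, 2))
  expect_equal(rfe_loss(inst$data, pr, inst$scores, alpha = 0),
               mdfa_loss(inst$data, pr, inst$scores))
  a <- 0.7
  expect_equal(rfe_loss(inst$data, pr, inst$scores, a),
               mdfa_loss(inst$data, pr, inst$scores) +
                 a * loop_regression_loss(inst$data$Y, inst$scores$F, pr$B),
               tolerance = 1e-12)
  d_noy <- fe_data(inst$data$X, center = FALSE)
  expect_error(rfe_loss(d_noy, pr, inst$scores, a), "mdfa_loss")
})

test_that("penalized form differs from the direct objective by alpha * ||Y||^2", {
  inst <- make_exact_instance(n = 30, p = 5, r = 2, q = 3, seed = 5)
  set.seed(11)
  pr <- fe_params(matrix(rnorm(10), 5, 2), runif(5), B = matrix(rnorm(6), 3, 2))
  for (a in c(0.01, 1, 4)) {
    expect_equal(rfe_loss(inst$data, pr, inst$scores, a) -
                   penalized_form_loss(inst$data, pr, inst$scores, a),
                 a * sum(inst$data$Y^2), tolerance = 1e-10)
  }
  # B = 0 kills both the ridge and the covariance-attraction terms
  pr0 <- fe_params(pr$A, pr$psi, B = matrix(0, 3, 2))
  expect_equal(penalized_form_loss(inst$data, pr0, inst$scores, 2),
               mdfa_loss(inst$data, pr0, inst$scores))
})

test_that("losses are invariant under a common orthogonal rotation of (A, B, F)", {
  inst <- make_exact_instance(n = 30, p = 5, r = 3, q = 3, seed = 6)
  set.seed(12)
  pr <- fe_params(matrix(rnorm(15), 5, 3), runif(5), B = matrix(rnorm(9), 3, 3))
  base <- rfe_loss(inst$data, pr, inst$scores, 0.5)
  for (s in 1:4) {
    T <- random_orthogonal(3, seed = 100 + s)
    pr_t <- fe_params(pr$A %*% T, pr$psi, pr$B %*% T)
    sc_t <- fe_scores(inst$scores$F %*% T, inst$scores$U)
    expect_true(check_constraint(sc_t)$ok)
    expect_equal(rfe_loss(inst$data, pr_t, sc_t, 0.5), base, tolerance = 1e-10)
  }
  # the regression term never helps below the pure factor term
  expect_gte(base + 1e-12, mdfa_loss(inst$data, pr, inst$scores))
})
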