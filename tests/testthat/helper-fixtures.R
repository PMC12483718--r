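# Shared fixture builders. Everything is generated in code under fixed
# seeds; no files.

# A random orthogonal r x r matrix (QR of a Gaussian draw, sign-fixed).
random_orthogonal <- function(r, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_d <- qr(matrix(rnorm(r * r), r, r))
  Q <- qr.Q(qr_d)
  Q %*% diag(sign(diag(qr.R(qr_d))), r)
}

# A valid constrained score set plus consistent parameters and the exact
# data X = F A' + U Psi (and Y = F B' when q > 0).
make_exact_instance <- function(n = 30, p = 4, r = 2, q = 2, seed = 1) {
  scores <- generate_true_scores(n, r, p, seed = seed)
  A <- simple_structure_loadings(p, r, 0.5, 1, seed = seed + 1)
  set.seed(seed + 2)
  psi <- runif(p, 0.3, 0.8)
  B <- if (q > 0) matrix(runif(q * r, 0.5, 1), q, r) else NULL
  X <- tcrossprod(scores$F, A) + sweep(scores$U, 2, psi, `*`)
  colnames(X) <- paste0("x", seq_len(p))
  Y <- if (q > 0) {
    Ym <- tcrossprod(scores$F, B)
    colnames(Ym) <- paste0("y", seq_len(q))
    Ym
  } else NULL
  list(data = fe_data(X, Y, center = FALSE),
       params = fe_params(A, psi, B), scores = scores)
}

# Brute-force loss oracles (double loops, no linear algebra shortcuts).
loop_mdfa_loss <- function(X, A, psi, F, U) {
  total <- 0
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(X))) {
      fitted <- sum(F[i, ] * A[j, ]) + U[i, j] * psi[j]
      total <- total + (X[i, j] - fitted)^2
    }
  }
  as.numeric(total)
}

loop_regression_loss <- function(Y, F, B) {
  total <- 0
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      total <- total + (Y[i, j] - sum(F[i, ] * B[j, ]))^2
    }
  }
  as.numeric(total)
}

cluster_agreement <- function(a, b) {
  tb <- table(a, b)
  sum(apply(tb, 1, max)) / length(a)
}

# Independent geomin criterion evaluation (direct formula, no gradients).
.vgq_geomin_for_test <- function(L, eps) {
  r <- ncol(L)
  sum(apply(L^2 + eps, 1, function(row) prod(row)^(1 / r)))
}
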