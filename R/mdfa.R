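# Plain matrix decomposition factor analysis and the split of the optimal
# factor scores into a determinate part (linear in X) and an indeterminate
# rotation of an orthogonal-complement basis.

#' Fit plain matrix decomposition factor analysis (MDFA)
#'
#' Minimizes `||X - F A' - U Psi||^2` over loadings, diagonal Psi, and
#' constrained scores `(1/n) [F U]'[F U] = I`, by the same alternating
#' scheme as [fit_rfe()] with the criterion block removed. The returned
#' common scores are one representative of an indeterminacy class: any
#' orthonormal frame orthogonal to the column space of `X` can replace the
#' unidentified score component without changing the loss (see
#' [decompose_scores()]).
#'
#' @inheritParams fit_rfe
#' @return An object of classes `mdfa_fit`/`fe_fit`; see [fit_rfe()].
#' @examples
#' demo <- generate_nocluster_demo(n = 80, seed = 2)
#' fit <- fit_mdfa(demo$data, r = 2, control = fe_control(n_starts = 5, seed = 2))
#' glance(fit)
#' @export
fit_mdfa <- function(data, r, control = fe_control()) {
  d <- .as_fe_data(data)
  X <- d$X
  n <- nrow(X); p <- ncol(X)
  .check_fit_dims(n, p, NULL, r)
  .rank_warn(X)
  ms <- .multistart(function() .als_run(X, NULL, r, control$alpha,
                                        control$tol, control$max_iter),
                    control)
  .new_fit(ms, d, r, control, class = "mdfa_fit")
}

#' Split MDFA factor scores into determinate and indeterminate parts
#'
#' At an MDFA solution with loadings `A` and uniqueness square roots
#' `psi`, write `W = [A, Psi]` and take the singular value decomposition
#' `X W = P1 L1 Q1' ` (rank p when `X` has full column rank). The optimal
#' constrained score block is
#' `Z(M) = sqrt(n) P1 Q1' + sqrt(n) P0 M Q0'`, where `Q0` spans the right
#' null space of `X W`, `P0` is any orthonormal n x r frame orthogonal to
#' the column space of `X`, and `M` ranges over orthogonal r x r matrices.
#' The first term is the uniquely determined part (a linear combination of
#' the columns of `X`); the second is the indeterminate part, along which
#' the loss and the constraint are exactly invariant. Use
#' [score_variant()] to materialize members of the class.
#'
#' @param fit A fitted `mdfa_fit` object (an `rfe_fit` is accepted, but
#'   its scores are already unique).
#' @param seed Integer seed used to pick the (arbitrary) orthonormal
#'   complement frame `P0` reproducibly. Default 1.
#' @return An object of class `fe_score_decomposition`: a list with
#'   `F_det` (n x r determinate common scores), `Z_det` (n x (r+p)),
#'   `basis_perp` (`P0`, n x r, orthonormal, orthogonal to `col(X)`),
#'   `Q0` ((r+p) x r right null basis), `singulars` (the p positive
#'   singular values of `X W`), `r`, `n`.
#' @export
decompose_scores <- function(fit, seed = 1) {
  stopifnot(inherits(fit, "fe_fit"))
  X <- fit$data$X
  n <- nrow(X); p <- ncol(X); r <- fit$r
  if (qr(X)$rank < p) {
    abort("`X` must have full column rank: the determinate/indeterminate score split is ill-defined otherwise.")
  }
  W <- cbind(fit$params$A, diag(fit$params$psi, p))
  sv <- svd(X %*% W)
  d_tol <- max(n, r + p) * .Machine$double.eps * max(sv$d[1], 1)
  pos <- sv$d > d_tol
  if (sum(pos) != p) {
    warn(sprintf("Expected %d positive singular values of X W, found %d; the weight block is rank deficient.",
                 p, sum(pos)))
  }
  keep <- seq_len(min(p, sum(pos)))
  P1 <- sv$u[, keep, drop = FALSE]
  Q1 <- sv$v[, keep, drop = FALSE]
  Q0 <- sv$v[, setdiff(seq_len(r + p), keep), drop = FALSE]
  Z_det <- sqrt(n) * tcrossprod(P1, Q1)

  # Orthonormal frame orthogonal to col(X), built deterministically from a
  # seeded Gaussian draw projected out of col(X) (no full n x n SVD).
  qr_x <- qr(X)
  P0 <- withr_seed(seed, {
    Gm <- matrix(rnorm(n * r), n, r)
    Res <- Gm - qr.fitted(qr_x, Gm)
    svd(Res)$u[, seq_len(r), drop = FALSE]
  })
  structure(list(F_det = Z_det[, seq_len(r), drop = FALSE],
                 Z_det = Z_det, basis_perp = P0, Q0 = Q0,
                 singulars = sv$d[keep], r = r, n = n),
            class = "fe_score_decomposition")
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Materialize one member of the MDFA score indeterminacy class
#'
#' @param decomp Result of [decompose_scores()].
#' @param M Orthogonal r x r matrix selecting the member; default identity.
#' @return An [fe_scores] object `Z(M) = Z_det + sqrt(n) P0 M Q0'`,
#'   satisfying the orthonormality constraint exactly and attaining the
#'   same loss as any other member.
#' @export
score_variant <- function(decomp, M = diag(decomp$r)) {
  stopifnot(inherits(decomp, "fe_score_decomposition"))
  r <- decomp$r
  if (!isTRUE(all.equal(crossprod(M), diag(r), tolerance = 1e-8))) {
    abort("`M` must be orthogonal (M'M = I).")
  }
  Z <- decomp$Z_det + sqrt(decomp$n) * decomp$basis_perp %*% M %*% t(decomp$Q0)
  fe_scores(Z[, seq_len(r), drop = FALSE],
            Z[, -seq_len(r), drop = FALSE])
}
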