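# Shared domain objects and loss evaluators for the matrix decomposition
# factor model X ~ F A' + U Psi, with the joint score block Z = [F U]
# constrained to (1/n) Z'Z = I.

#' Bundle common and unique factor scores
#'
#' The factor model constrains the joint score block `Z = [F U]` to be
#' column-orthonormal after scaling by `sqrt(n)`: `(1/n) Z'Z = I`. This
#' constructor checks shapes; use [check_constraint()] to test the
#' orthonormality itself.
#'
#' @param F Numeric matrix n x r of common factor scores.
#' @param U Numeric matrix n x p of unique factor scores.
#' @return An object of class `fe_scores` with elements `F` and `U`.
#' @export
fe_scores <- function(F, U) {
  F <- .as_numeric_matrix(F, "F")
  U <- .as_numeric_matrix(U, "U")
  if (nrow(F) != nrow(U)) {
    abort(sprintf("`F` has %d rows but `U` has %d; scores describe the same observations.",
                  nrow(F), nrow(U)))
  }
  structure(list(F = F, U = U), class = "fe_scores")
}

#' Bundle factor-model parameter matrices
#'
#' @param A Loading matrix p x r.
#' @param psi Length-p nonnegative vector: the square roots of the
#'   uniquenesses (the diagonal of the Psi matrix). Uniqueness itself is
#'   `psi^2`.
#' @param B Optional q x r matrix of regression coefficients of the external
#'   criteria on the common factors (absent for plain MDFA).
#' @return An object of class `fe_params` with elements `A`, `psi`, `B`.
#' @export
fe_params <- function(A, psi, B = NULL) {
  A <- .as_numeric_matrix(A, "A")
  psi <- as.numeric(psi)
  if (length(psi) != nrow(A)) {
    abort(sprintf("`psi` has length %d but `A` has %d rows.", length(psi), nrow(A)))
  }
  if (any(psi < 0)) abort("`psi` entries must be nonnegative (square roots of uniquenesses).")
  if (!is.null(B)) {
    B <- .as_numeric_matrix(B, "B")
    if (ncol(B) != ncol(A)) abort("`B` must have the same number of columns (factors) as `A`.")
  }
  structure(list(A = A, psi = psi, B = B), class = "fe_params")
}

#' Check the score orthonormality constraint
#'
#' Tests whether `(1/n) Z'Z = I` for the joint score block `Z = [F U]`,
#' the constraint under which every estimator in the package operates.
#'
#' @param scores An [fe_scores] object.
#' @param tol Maximum allowed absolute deviation of any entry of
#'   `(1/n) Z'Z` from the identity. Default `1e-6`.
#' @return A list with `ok` (logical) and `max_deviation` (numeric).
#' @examples
#' z <- qr.Q(qr(matrix(rnorm(60), 10)))  # 10 x 6 orthonormal
#' s <- fe_scores(sqrt(10) * z[, 1:2], sqrt(10) * z[, 3:6])
#' check_constraint(s)
#' @export
check_constraint <- function(scores, tol = 1e-6) {
  stopifnot(inherits(scores, "fe_scores"))
  Z <- cbind(scores$F, scores$U)
  n <- nrow(Z)
  G <- crossprod(Z) / n
  dev <- max(abs(G - diag(ncol(Z))))
  list(ok = dev <= tol, max_deviation = dev)
}

#' Factor-model least squares loss
#'
#' The squared Frobenius norm `||X - F A' - U Psi||^2` that MDFA minimizes.
#'
#' @param data An [fe_data] bundle (or centered matrix/data frame).
#' @param params An [fe_params] object.
#' @param scores An [fe_scores] object.
#' @return Nonnegative scalar.
#' @export
mdfa_loss <- function(data, params, scores) {
  d <- .as_fe_data(data)
  .check_dims(d, params, scores)
  R <- d$X - tcrossprod(scores$F, params$A) -
    sweep(scores$U, 2, params$psi, `*`)
  sum(R^2)
}

#' Regression-penalized factor loss
#'
#' The RFE objective `||X - F A' - U Psi||^2 + alpha * ||Y - F B'||^2`:
#' the MDFA loss plus `alpha` times the multivariate-regression loss of the
#' external criteria on the common factor scores.
#'
#' @inheritParams mdfa_loss
#' @param alpha Positive tuning parameter balancing the two terms. A value
#'   of 0 is accepted for diagnostic evaluation only.
#' @return Nonnegative scalar.
#' @export
rfe_loss <- function(data, params, scores, alpha) {
  d <- .as_fe_data(data)
  if (is.null(d$Y)) {
    abort("rfe_loss() needs external criteria `y`; use mdfa_loss() when there are none.")
  }
  if (is.null(params$B)) abort("`params$B` is required to evaluate the regression term.")
  if (alpha < 0) abort("`alpha` must be nonnegative.")
  mdfa_loss(d, params, scores) +
    alpha * sum((d$Y - tcrossprod(scores$F, params$B))^2)
}

#' RFE objective in penalized-factor-analysis form
#'
#' Re-expresses the regression term of the RFE objective, for scores
#' satisfying the orthonormality constraint, as a ridge penalty on the
#' coefficients minus a covariance attraction term:
#' `alpha * n * ||B||^2 - 2 * alpha * n * tr(B' V)` with
#' `V = (1/n) Y'F`, dropping the constant `alpha * ||Y||^2`. The value
#' returned therefore differs from [rfe_loss()] by exactly that constant;
#' the identity is used as an internal cross-check of the estimator.
#'
#' @inheritParams rfe_loss
#' @return Scalar (can be negative: the constant term is omitted).
#' @export
penalized_form_loss <- function(data, params, scores, alpha) {
  d <- .as_fe_data(data)
  if (is.null(d$Y)) abort("penalized_form_loss() needs external criteria `y`.")
  if (is.null(params$B)) abort("`params$B` is required.")
  n <- nrow(d$X)
  V <- crossprod(d$Y, scores$F) / n
  mdfa_loss(d, params, scores) +
    alpha * n * sum(params$B^2) - 2 * alpha * n * sum(params$B * V)
}

.check_dims <- function(d, params, scores) {
  n <- nrow(d$X); p <- ncol(d$X)
  if (nrow(scores$F) != n) abort("Scores and data disagree on the number of observations.")
  if (ncol(scores$U) != p) abort("`U` must have one column per observed variable.")
  if (nrow(params$A) != p) abort("`A` must have one row per observed variable.")
  if (ncol(params$A) != ncol(scores$F)) abort("`A` and `F` disagree on the number of factors.")
  if (!is.null(params$B) && !is.null(d$Y)) {
    if (nrow(params$B) != ncol(d$Y)) abort("`B` must have one row per external criterion.")
  }
  invisible(TRUE)
}

#' Algorithm settings for the alternating least squares estimators
#'
#' @param alpha Positive tuning parameter (weight of the regression or
#'   clustering penalty). Default 0.01: the estimators are designed for a
#'   small fixed value, which keeps the factor-analytic part dominant while
#'   still pinning down the scores.
#' @param n_starts Number of random initializations; the best converged
#'   solution is kept and the spread across starts is reported. Default 20.
#' @param tol Convergence threshold on the per-iteration decrease of the
#'   objective, normalized by the squared norm of the (augmented) data
#'   block. Default 1e-7.
#' @param max_iter Iteration cap per start. Default 1000.
#' @param seed Integer seed; start `s` uses `seed + s` so runs are exactly
#'   reproducible. Default 1.
#' @param local_threshold Relative excess over the best converged loss above
#'   which a start is counted as a local solution. Default 1e-4.
#' @return A list of class `fe_control`.
#' @export
fe_control <- function(alpha = 0.01, n_starts = 20, tol = 1e-7,
                       max_iter = 1000, seed = 1, local_threshold = 1e-4) {
  if (alpha <= 0) abort("`alpha` must be positive.")
  if (tol <= 0) abort("`tol` must be positive.")
  if (n_starts < 1 || max_iter < 1) abort("`n_starts` and `max_iter` must be at least 1.")
  structure(list(alpha = alpha, n_starts = as.integer(n_starts), tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 local_threshold = local_threshold),
            class = "fe_control")
}
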