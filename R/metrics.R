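# Evaluation statistics: matrix recovery error, multi-start diagnostics,
# post-hoc Bartlett scores, score comparisons, standardized group
# differences, and per-observation residuals.

#' Root mean square error of approximation between two matrices
#'
#' `sqrt(mean((M_hat - M_true)^2))`: the element-wise recovery error used
#' to score how well an estimated parameter matrix reproduces its true
#' counterpart. Columns must already be aligned (see [align_for_rmsea()]).
#'
#' @param M_hat,M_true Numeric matrices (or vectors) of identical dimension.
#' @return Nonnegative scalar.
#' @export
rmsea <- function(M_hat, M_true) {
  if (is.vector(M_hat)) M_hat <- matrix(M_hat)
  if (is.vector(M_true)) M_true <- matrix(M_true)
  if (!all(dim(M_hat) == dim(M_true))) abort("Matrices must have identical dimensions.")
  sqrt(mean((M_hat - M_true)^2))
}

#' Proportion of multi-start runs that ended in a local solution
#'
#' A start counts as local when its converged loss exceeds the best loss
#' across starts by more than `threshold` in relative terms:
#' `(f_j - f_min) / f_min > threshold`.
#'
#' @param start_losses Numeric vector of converged loss values, one per
#'   start.
#' @param threshold Relative excess over the minimum. Default 1e-4.
#' @return Proportion in `[0, 1]`.
#' @export
local_solution_proportion <- function(start_losses, threshold = 1e-4) {
  if (length(start_losses) == 0) abort("`start_losses` must not be empty.")
  f_min <- min(start_losses)
  if (f_min == 0) return(mean(start_losses > threshold))
  mean((start_losses - f_min) / f_min > threshold)
}

#' Bartlett factor scores
#'
#' The weighted-least-squares estimator
#' `F = X Psi^-2 A (A' Psi^-2 A)^-1`, i.e. the row-wise generalized least
#' squares solution of `x_i = A f_i + Psi u_i` weighting by the inverse
#' uniquenesses. The scores are a linear map of `X` alone - the classical
#' post-hoc contrast to RFE scores, which are linear in `[X, Y]`. A factor
#' correlation matrix `phi` from an oblique rotation may be supplied; it is
#' validated (symmetric, unit diagonal) for interface completeness but the
#' WLS estimator itself does not depend on it.
#'
#' @param x Centered data matrix or data frame (n x p).
#' @param A Loading matrix p x r.
#' @param psi Length-p vector of uniqueness square roots, all strictly
#'   positive (a near-zero entry - a Heywood-adjacent case - is an error
#'   naming the variable).
#' @param phi Optional r x r factor correlation matrix.
#' @return n x r matrix of factor scores.
#' @export
bartlett_scores <- function(x, A, psi, phi = NULL) {
  X <- .as_numeric_matrix(x, "x")
  A <- .as_numeric_matrix(A, "A")
  psi <- as.numeric(psi)
  if (length(psi) != nrow(A)) abort("`psi` must have one entry per variable.")
  tiny <- psi < 1e-8
  if (any(tiny)) {
    nm <- colnames(X) %||% paste0("x", seq_along(psi))
    abort(sprintf("Near-zero uniqueness for variable(s) %s: Bartlett weights are undefined.",
                  paste(nm[tiny], collapse = ", ")))
  }
  if (!is.null(phi)) {
    if (!all(dim(phi) == ncol(A)) || max(abs(diag(as.matrix(phi)) - 1)) > 1e-8) {
      abort("`phi` must be an r x r correlation matrix with unit diagonal.")
    }
  }
  Wp <- A / psi^2                    # Psi^-2 A
  X %*% Wp %*% solve(crossprod(A, Wp))
}

#' Column-wise Pearson correlations between two score matrices
#'
#' @param F1,F2 Score matrices with matched (aligned) columns.
#' @return Numeric vector of length r.
#' @export
score_correlations <- function(F1, F2) {
  F1 <- .as_numeric_matrix(F1, "F1")
  F2 <- .as_numeric_matrix(F2, "F2")
  if (!all(dim(F1) == dim(F2))) abort("Score matrices must have identical dimensions.")
  if (any(apply(F1, 2, sd) == 0) || any(apply(F2, 2, sd) == 0)) {
    abort("Zero-variance column: correlation undefined.")
  }
  vapply(seq_len(ncol(F1)), function(j) cor(F1[, j], F2[, j]), numeric(1))
}

#' Cohen's d with a large-sample confidence interval
#'
#' Pooled-standard-deviation standardized mean difference between two
#' groups, with the normal-approximation interval
#' `d +/- z * sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2)))`.
#'
#' @param scores_group1,scores_group2 Numeric vectors (each of length >= 2).
#' @param level Confidence level. Default 0.95.
#' @return A tibble with columns `d`, `lower`, `upper`.
#' @export
cohens_d_ci <- function(scores_group1, scores_group2, level = 0.95) {
  g1 <- as.numeric(scores_group1); g2 <- as.numeric(scores_group2)
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) abort("Both groups need at least two observations.")
  sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
  if (sp2 == 0) abort("Zero pooled standard deviation: d is undefined.")
  d <- (mean(g1) - mean(g2)) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(d = d, lower = d - z * se, upper = d + z * se)
}

#' Per-observation residual norms of a fitted factor model
#'
#' The Euclidean norm of each row of `X - F A' - U Psi`. With uniquely
#' determined scores these are themselves unique, so they can be read as
#' the degree to which each observation departs from the factor model
#' (e.g. to flag outlying respondents). Their squared sum equals the
#' factor-model part of the loss.
#'
#' @param fit A fitted `fe_fit` object.
#' @return A tibble with `row_id` and `residual`.
#' @export
individual_residuals <- function(fit) {
  stopifnot(inherits(fit, "fe_fit"))
  R <- fit$data$X - tcrossprod(fit$scores$F, fit$params$A) -
    sweep(fit$scores$U, 2, fit$params$psi, `*`)
  tibble::tibble(row_id = fit$data$row_ids, residual = sqrt(rowSums(R^2)))
}

#' Recovery report for a fit against known truth
#'
#' Reports the RMSEA of each parameter matrix against its generating value
#' plus the local-solution proportion of the fit. The constrained
#' estimators determine the loadings, coefficients and common scores only
#' up to a common orthogonal rotation, so by default a single orthogonal
#' Procrustes transformation is computed from the loadings and applied
#' consistently to `A`, `B` and `F` before comparing
#' (`align = "procrustes"`); `align = "permutation-sign"` restricts the
#' alignment to column permutations and sign flips, which is only
#' appropriate when the estimate is already in the truth's orientation.
#' Uniqueness is compared on the `psi^2` vectors.
#'
#' @param fit A fitted `fe_fit`.
#' @param truth A truth bundle as returned by [generate_dataset()] (fields
#'   `A`, `psi`, `B`, `F`, `U`).
#' @param align `"procrustes"` (default) or `"permutation-sign"`.
#' @return One-row tibble with `rmsea_A`, `rmsea_F`, `rmsea_U`, `rmsea_B`,
#'   `rmsea_uniqueness`, `local_solution_proportion`.
#' @export
recovery_report <- function(fit, truth,
                            align = c("procrustes", "permutation-sign")) {
  stopifnot(inherits(fit, "fe_fit"))
  align <- match.arg(align)
  if (align == "procrustes") {
    T <- procrustes_align(fit$params$A, truth$A)$T
    A_al <- fit$params$A %*% T
    F_al <- fit$scores$F %*% T
    B_al <- if (!is.null(fit$params$B) && !is.null(truth$B)) fit$params$B %*% T else NULL
  } else {
    A_al <- align_for_rmsea(fit$params$A, truth$A)
    perm <- attr(A_al, "perm"); sgn <- attr(A_al, "signs")
    F_al <- sweep(fit$scores$F[, perm, drop = FALSE], 2, sgn, `*`)
    B_al <- if (!is.null(fit$params$B) && !is.null(truth$B)) {
      sweep(fit$params$B[, perm, drop = FALSE], 2, sgn, `*`)
    } else NULL
  }
  tibble::tibble(
    rmsea_A = rmsea(A_al, truth$A),
    rmsea_F = rmsea(F_al, truth$F),
    rmsea_U = rmsea(fit$scores$U, truth$U),
    rmsea_B = if (!is.null(B_al)) rmsea(B_al, truth$B) else NA_real_,
    rmsea_uniqueness = rmsea(fit$params$psi^2, truth$psi^2),
    local_solution_proportion = fit$local_solution_proportion
  )
}
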