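# Post-fit transformations. The fitted loadings, coefficients and scores
# are indeterminate with respect to nonsingular r x r transformations T
# applied as A -> A T^-T', B -> B T^-T', F -> F T (which leaves F A' and
# the whole objective unchanged); geomin rotation selects an interpretable
# member of that class. Orthogonal Procrustes alignment makes score
# matrices from different runs or methods comparable.

# geomin criterion and gradient for a loading matrix L (p x r):
# q(L) = sum_j (prod_l (L_jl^2 + eps))^(1/r)
.vgq_geomin <- function(L, eps) {
  r <- ncol(L)
  L2 <- L^2 + eps
  pro <- exp(rowSums(log(L2)) / r)
  list(f = sum(pro), Gq = (2 / r) * (L / L2) * pro)
}

# Oblique gradient projection (Bernaards & Jennrich). T has unit-length
# columns; the rotated loadings are L = A (T')^-1.
.gpa_oblique <- function(A, eps, T0, max_iter = 500, tol = 1e-8) {
  T <- T0
  al <- 1
  Ti <- solve(T)
  L <- A %*% t(Ti)
  vg <- .vgq_geomin(L, eps)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  for (it in seq_len(max_iter)) {
    Gp <- G - T %*% diag(colSums(T * G), ncol(T))
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    improved <- FALSE
    for (half in 1:20) {
      X <- T - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Tti <- tryCatch(solve(Tt), error = function(e) NULL)
      if (!is.null(Tti)) {
        Lt <- A %*% t(Tti)
        vgt <- .vgq_geomin(Lt, eps)
        if (vgt$f < f - 0.5 * s^2 * al) {
          T <- Tt; Ti <- Tti; L <- Lt
          f <- vgt$f
          G <- -t(t(L) %*% vgt$Gq %*% Tti)
          improved <- TRUE
          break
        }
      }
      al <- al / 2
    }
    if (!improved) break
  }
  list(T = T, L = L, f = f, iterations = it)
}

.random_oblique_start <- function(r) {
  M <- matrix(rnorm(r * r), r, r)
  M %*% diag(1 / sqrt(colSums(M^2)), r)
}

#' Geomin oblique rotation with consistent counter-rotation
#'
#' Minimizes the geomin criterion
#' `sum_j (prod_l (a_jl^2 + eps))^(1/r)` over oblique rotations of the
#' loading matrix by gradient projection, restarted from random initial
#' transformations. The scores (and criterion coefficients, when present)
#' are counter-transformed so the model reconstruction `F A'` is exactly
#' preserved.
#'
#' @param x A p x r loading matrix, or a fitted `fe_fit` object (then the
#'   scores and `B` are counter-rotated too).
#' @param eps Geomin constant added to the squared loadings. Default 0.01.
#' @param n_starts Number of random initial rotations (plus the identity).
#'   Default 30.
#' @param max_iter Gradient-projection iteration cap per start.
#' @param seed Seed for the random starts. Default 1.
#' @return A list of class `fe_rotation`: `T` (oblique transformation,
#'   unit-length columns), `A_rot`, `phi` (factor correlations `T'T`),
#'   `criterion_value`, `converged`; plus `F_rot` and `B_rot` when a fit
#'   was supplied.
#' @examples
#' A <- rbind(matrix(c(.8, 0), 3, 2, byrow = TRUE),
#'            matrix(c(0, .7), 3, 2, byrow = TRUE))
#' rot <- geomin_rotate(A %*% matrix(c(1, .4, 0, 1), 2))
#' round(rot$A_rot, 2)
#' @export
geomin_rotate <- function(x, eps = 0.01, n_starts = 30, max_iter = 500,
                          seed = 1) {
  fit <- NULL
  if (inherits(x, "fe_fit")) {
    fit <- x
    A <- fit$params$A
  } else {
    A <- .as_numeric_matrix(x, "x")
  }
  r <- ncol(A)
  if (r < 2) abort("Rotation needs at least two factors.")
  best <- .gpa_oblique(A, eps, diag(r), max_iter = max_iter)
  withr_seed(seed, {
    for (s in seq_len(n_starts)) {
      cand <- .gpa_oblique(A, eps, .random_oblique_start(r), max_iter = max_iter)
      if (cand$f < best$f) best <- cand
    }
  })
  converged <- best$iterations < max_iter
  if (!converged) {
    warn("Geomin rotation hit the iteration cap; returning the best iterate.")
  }
  out <- list(T = best$T, A_rot = best$L, phi = crossprod(best$T),
              criterion_value = best$f, converged = converged)
  if (!is.null(fit)) {
    out$F_rot <- fit$scores$F %*% best$T
    if (!is.null(fit$params$B)) out$B_rot <- fit$params$B %*% t(solve(best$T))
  }
  structure(out, class = "fe_rotation")
}

#' Orthogonal Procrustes alignment of score matrices
#'
#' Finds the orthogonal `T` minimizing `||F_source T - F_target||^2` via
#' the singular value decomposition of `F_source' F_target`, and returns
#' the aligned scores.
#'
#' @param F_source,F_target Numeric matrices of identical dimension.
#' @return A list with `T` (orthogonal r x r), `aligned`
#'   (`F_source %*% T`), and `residual` (Frobenius norm after alignment).
#' @export
procrustes_align <- function(F_source, F_target) {
  Fs <- .as_numeric_matrix(F_source, "F_source")
  Ft <- .as_numeric_matrix(F_target, "F_target")
  if (!all(dim(Fs) == dim(Ft))) abort("Score matrices must have identical dimensions.")
  M <- crossprod(Fs, Ft)
  sv <- svd(M)
  if (sv$d[length(sv$d)] <= max(dim(M)) * .Machine$double.eps * max(sv$d[1], 1)) {
    warn("Cross-product is rank deficient: the Procrustes rotation is not unique.")
  }
  T <- tcrossprod(sv$u, sv$v)
  aligned <- Fs %*% T
  list(T = T, aligned = aligned, residual = sqrt(sum((aligned - Ft)^2)))
}

# All 2^r sign patterns as a matrix (rows = patterns).
.sign_patterns <- function(r) {
  as.matrix(expand.grid(rep(list(c(1, -1)), r)))
}

#' Align an estimated matrix to its truth before computing RMSEA
#'
#' Matrix recovery error is only meaningful once the column order and signs
#' (or an orthogonal rotation) of the estimate are matched to the
#' reference. In `"permutation-sign"` mode every column permutation and
#' sign flip is searched exhaustively (feasible for r <= 8; beyond that a
#' greedy match is used with a warning); in `"procrustes"` mode the
#' orthogonal Procrustes solution is applied.
#'
#' @param M_est,M_true Matrices of identical dimension.
#' @param mode `"permutation-sign"` (default) or `"procrustes"`.
#' @return The aligned estimate, with attributes `perm` and `signs`
#'   (permutation-sign mode) or `T` (procrustes mode).
#' @export
align_for_rmsea <- function(M_est, M_true, mode = c("permutation-sign", "procrustes")) {
  mode <- match.arg(mode)
  E <- .as_numeric_matrix(M_est, "M_est")
  Tm <- .as_numeric_matrix(M_true, "M_true")
  if (!all(dim(E) == dim(Tm))) abort("Matrices must have identical dimensions.")
  r <- ncol(E)
  if (mode == "procrustes") {
    pr <- procrustes_align(E, Tm)
    out <- pr$aligned
    attr(out, "T") <- pr$T
    return(out)
  }
  if (r > 8) {
    warn("More than 8 columns: using greedy column matching instead of exhaustive search.")
    return(.greedy_align(E, Tm))
  }
  perms <- .permutations(r)
  signs <- .sign_patterns(r)
  best <- NULL; best_err <- Inf
  for (i in seq_len(nrow(perms))) {
    Ep <- E[, perms[i, ], drop = FALSE]
    for (j in seq_len(nrow(signs))) {
      Es <- sweep(Ep, 2, signs[j, ], `*`)
      err <- sum((Es - Tm)^2)
      if (err < best_err) {
        best_err <- err
        best <- Es
        attr(best, "perm") <- perms[i, ]
        attr(best, "signs") <- unname(signs[j, ])
      }
    }
  }
  best
}

.permutations <- function(r) {
  if (r == 1) return(matrix(1))
  sub <- .permutations(r - 1)
  do.call(rbind, lapply(seq_len(r), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

.greedy_align <- function(E, Tm) {
  r <- ncol(E)
  used <- integer(0)
  perm <- integer(r); sgn <- numeric(r)
  for (j in seq_len(r)) {
    errs <- vapply(seq_len(r), function(i) {
      if (i %in% used) return(Inf)
      min(sum((E[, i] - Tm[, j])^2), sum((-E[, i] - Tm[, j])^2))
    }, numeric(1))
    i <- which.min(errs)
    perm[j] <- i
    sgn[j] <- if (sum((E[, i] - Tm[, j])^2) <= sum((-E[, i] - Tm[, j])^2)) 1 else -1
    used <- c(used, i)
  }
  out <- sweep(E[, perm, drop = FALSE], 2, sgn, `*`)
  attr(out, "perm") <- perm
  attr(out, "signs") <- sgn
  out
}
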