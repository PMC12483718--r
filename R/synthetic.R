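# Synthetic-data generators. Three designs: (i) the factor-regression
# simulation used to study parameter recovery (orthonormal true scores,
# simple-structure loadings, error scaled to an exact explained-variance
# proportion rho); (ii) a cluster-free demonstration dataset on which a
# sound score-identification method should NOT invent clusters; (iii) a
# planted-cluster variant for testing cluster recovery.

#' Describe a recovery-simulation condition
#'
#' Defaults give the desk-scale study condition: n = 200 observations,
#' p = 12 observed variables, r = 3 factors, q = 3 external criteria,
#' nonzero loadings and criterion coefficients drawn from Uniform(0.5, 1)
#' with random signs, true uniqueness square roots all 0.5, and explained
#' variance rho from the three-level grid {0.5, 0.7, 0.9}.
#'
#' @param n,p,q,r Dimensions: observations, observed variables, external
#'   criteria, common factors.
#' @param rho Explained-variance proportion in (0, 1]: the model part of
#'   each generated matrix accounts for exactly this share of the total
#'   sum of squares. `rho = 1` gives noise-free data.
#' @param loading_low,loading_high Bounds of the uniform distribution for
#'   nonzero loadings (and for the entries of the true `B`).
#' @param psi_true Length-p vector of true uniqueness square roots.
#' @param seed Integer seed.
#' @return A list of class `fe_design`.
#' @export
simulation_design <- function(n = 200, p = 12, q = 3, r = 3, rho = 0.7,
                              loading_low = 0.5, loading_high = 1,
                              psi_true = rep(0.5, p), seed = 1) {
  if (rho <= 0 || rho > 1) abort("`rho` must be in (0, 1].")
  if (n <= p + r) abort("Need n > p + r.")
  if (length(psi_true) != p || any(psi_true < 0)) {
    abort("`psi_true` must be a length-p nonnegative vector.")
  }
  structure(list(n = n, p = p, q = q, r = r, rho = rho,
                 loading_low = loading_low, loading_high = loading_high,
                 psi_true = psi_true, seed = as.integer(seed)),
            class = "fe_design")
}

#' Generate true factor scores satisfying the constraint exactly
#'
#' Draws an n x (r+p) matrix from Uniform(0, 1), column-standardizes it,
#' takes its left singular vectors and scales by `sqrt(n)`: the resulting
#' block `Z = [F U]` satisfies `(1/n) Z'Z = I` exactly and has mean-zero
#' columns (they lie in the column space of a centered matrix).
#'
#' @param n,r,p Dimensions (requires `n > r + p`).
#' @param seed Integer seed.
#' @return An [fe_scores] object.
#' @export
generate_true_scores <- function(n, r, p, seed = 1) {
  if (n <= r + p) abort("Need n > r + p.")
  withr_seed(seed, {
    B0 <- matrix(runif(n * (r + p)), n, r + p)
    B0 <- scale(B0)
    Z <- sqrt(n) * svd(B0, nu = r + p, nv = 0)$u
    fe_scores(Z[, seq_len(r), drop = FALSE], Z[, -seq_len(r), drop = FALSE])
  })
}

#' Simple-structure loading matrix
#'
#' Perfect-cluster pattern: the p variables are split into r consecutive
#' blocks (the last block absorbs the remainder when p is not divisible
#' by r) and each variable loads on exactly one factor, with the nonzero
#' loading drawn from Uniform(low, high) and a random sign.
#'
#' @param p,r Dimensions (`r <= p`).
#' @param low,high Bounds for the nonzero magnitudes.
#' @param seed Integer seed.
#' @return p x r matrix.
#' @export
simple_structure_loadings <- function(p, r, low = 0.5, high = 1, seed = 1) {
  if (r > p) abort("`r` must not exceed `p`.")
  block <- rep(seq_len(r), each = ceiling(p / r))[seq_len(p)]
  withr_seed(seed, {
    A <- matrix(0, p, r)
    A[cbind(seq_len(p), block)] <-
      runif(p, low, high) * sample(c(-1, 1), p, replace = TRUE)
    A
  })
}

#' Scale an error matrix to an exact explained-variance proportion
#'
#' Returns `c * raw_error` with `c` chosen so that
#' `||model||^2 / (||model||^2 + ||c * raw_error||^2) = rho` exactly.
#'
#' @param model_part Model matrix (signal).
#' @param raw_error Unscaled error matrix of the same dimension.
#' @param rho Target explained-variance proportion in (0, 1].
#' @return Scaled error matrix.
#' @export
scale_error_to_rho <- function(model_part, raw_error, rho) {
  if (rho <= 0 || rho > 1) abort("`rho` must be in (0, 1].")
  if (!all(dim(model_part) == dim(raw_error))) abort("Shapes must match.")
  if (rho == 1) return(raw_error * 0)
  se <- sum(raw_error^2)
  if (se == 0) abort("`raw_error` must be nonzero.")
  sm <- sum(model_part^2)
  sqrt(sm * (1 - rho) / (rho * se)) * raw_error
}

#' Generate one simulated dataset plus its generating truth
#'
#' Builds orthonormal true scores, a simple-structure loading matrix, a
#' dense criterion coefficient matrix `B` (entries Uniform(low, high) with
#' random signs), and forms `X = F A' + U Psi + E_x` and `Y = F B' + E_y`
#' with standard normal errors scaled so the model part of each matrix
#' explains exactly `rho` of its sum of squares. Both matrices are then
#' column-centered.
#'
#' @param design An [simulation_design()] object.
#' @return A list with `data` (an [fe_data] bundle with `X` and `Y`) and
#'   `truth` (list with `F`, `U`, `A`, `psi`, `B`, `rho`).
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "fe_design"))
  n <- design$n; p <- design$p; q <- design$q; r <- design$r
  scores <- generate_true_scores(n, r, p, seed = design$seed)
  A <- simple_structure_loadings(p, r, design$loading_low, design$loading_high,
                                 seed = design$seed + 1)
  out <- withr_seed(design$seed + 2, {
    B <- matrix(runif(q * r, design$loading_low, design$loading_high) *
                  sample(c(-1, 1), q * r, replace = TRUE), q, r)
    model_x <- tcrossprod(scores$F, A) + sweep(scores$U, 2, design$psi_true, `*`)
    Ex <- scale_error_to_rho(model_x, matrix(rnorm(n * p), n, p), design$rho)
    model_y <- tcrossprod(scores$F, B)
    Ey <- scale_error_to_rho(model_y, matrix(rnorm(n * q), n, q), design$rho)
    list(X = model_x + Ex, Y = model_y + Ey, B = B)
  })
  colnames(out$X) <- paste0("x", seq_len(p))
  colnames(out$Y) <- paste0("y", seq_len(q))
  list(data = fe_data(out$X, out$Y, center = TRUE),
       truth = list(F = scores$F, U = scores$U, A = A,
                    psi = design$psi_true, B = out$B, rho = design$rho))
}

#' Cluster-free demonstration data
#'
#' Continuous (cluster-free) orthonormal true scores pushed through a
#' fixed two-factor, six-variable model: perfect simple structure with
#' loadings 0.8, uniqueness square roots `sqrt(1 - 0.8^2) = 0.6` (the
#' standardized-variable convention), and Uniform(-1, 1) residuals. On
#' such data a score-identification method should not produce sharply
#' separated score clusters - there are none.
#'
#' @param n Number of observations. Default 200.
#' @param seed Integer seed.
#' @return A list with `data` (an [fe_data] bundle, `X` only) and `truth`
#'   (list with `F`, `U`, `A`, `psi`).
#' @export
generate_nocluster_demo <- function(n = 200, seed = 1) {
  r <- 2; p <- 6
  A <- kronecker(diag(r), matrix(0.8, p / r, 1))
  psi <- rep(sqrt(1 - 0.8^2), p)
  scores <- generate_true_scores(n, r, p, seed = seed)
  X <- withr_seed(seed + 1, {
    tcrossprod(scores$F, A) + sweep(scores$U, 2, psi, `*`) +
      matrix(runif(n * p, -1, 1), n, p)
  })
  colnames(X) <- paste0("x", seq_len(p))
  list(data = fe_data(X, center = TRUE),
       truth = list(F = scores$F, U = scores$U, A = A, psi = psi))
}

# Regular simplex with k vertices, centered, embedded in r dimensions,
# scaled so all pairwise vertex distances equal `separation`.
.simplex_centroids <- function(k, r, separation) {
  V <- diag(k) - 1 / k
  sv <- svd(V)
  coords <- sv$u[, seq_len(k - 1), drop = FALSE] %*% diag(sv$d[seq_len(k - 1)], k - 1)
  if (k - 1 > r) {
    warn("k - 1 exceeds r: simplex centroids are projected, pairwise distances are only approximate.")
    coords <- coords[, seq_len(r), drop = FALSE]
  } else if (k - 1 < r) {
    coords <- cbind(coords, matrix(0, k, r - (k - 1)))
  }
  d0 <- sqrt(sum((coords[1, ] - coords[2, ])^2))
  if (separation > 0) coords * separation / d0 else coords * 0
}

#' Planted-cluster demonstration data
#'
#' Score clusters at the vertices of a regular simplex (pairwise centroid
#' distance `separation`) with Gaussian within-cluster spread, whitened to
#' satisfy the score constraint exactly (whitening is linear, so the
#' cluster geometry survives), then pushed through the same fixed
#' two-factor measurement model as [generate_nocluster_demo()]
#' (generalized to `r` factors and `3 r` variables).
#'
#' @param n Number of observations.
#' @param r Number of factors. Default 2.
#' @param k Number of planted clusters (`k >= 2`).
#' @param separation Pairwise distance between cluster centroids in the
#'   raw score space (before whitening). `0` collapses to the cluster-free
#'   case.
#' @param within_sd Within-cluster standard deviation of the raw scores.
#'   Default 0.35.
#' @param noise_half_width Half-width of the uniform measurement residuals
#'   added to `X`. Default 1 (as in the cluster-free demo); reduce it for
#'   cleanly separable benchmarks.
#' @param seed Integer seed.
#' @return A list with `data`, `truth` (scores and parameters), `cluster`
#'   (true memberships) and `centroids` (true whitened-space centroids).
#' @export
generate_clustered_demo <- function(n, r = 2, k = 3, separation = 4,
                                    within_sd = 0.35, noise_half_width = 1,
                                    seed = 1) {
  if (k < 2) abort("`k` must be at least 2.")
  p <- 3 * r
  A <- kronecker(diag(r), matrix(0.8, 3, 1))
  psi <- rep(sqrt(1 - 0.8^2), p)
  out <- withr_seed(seed, {
    cl <- sample(rep_len(seq_len(k), n))
    centers <- .simplex_centroids(k, r, separation)
    F_raw <- centers[cl, , drop = FALSE] + matrix(rnorm(n * r, sd = within_sd), n, r)
    F_raw <- scale(F_raw, center = TRUE, scale = FALSE)
    Fw <- F_raw %*% .inv_sqrt(crossprod(F_raw) / n)
    U_raw <- scale(matrix(runif(n * p, -1, 1), n, p), center = TRUE, scale = FALSE)
    U_proj <- U_raw - Fw %*% solve(crossprod(Fw), crossprod(Fw, U_raw))
    Uw <- U_proj %*% .inv_sqrt(crossprod(U_proj) / n)
    E <- matrix(runif(n * p, -noise_half_width, noise_half_width), n, p)
    list(cl = cl, Fw = Fw, Uw = Uw,
         X = tcrossprod(Fw, A) + sweep(Uw, 2, psi, `*`) + E)
  })
  colnames(out$X) <- paste0("x", seq_len(p))
  centroids <- .centroid_update(out$Fw, out$cl, k)
  list(data = fe_data(out$X, center = TRUE),
       truth = list(F = out$Fw, U = out$Uw, A = A, psi = psi),
       cluster = out$cl, centroids = centroids)
}

# Symmetric positive definite inverse square root.
.inv_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= 0)) abort("Matrix is not positive definite.")
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}
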