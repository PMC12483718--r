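# Clustering-based factor exploration (CFE): RFE with the regression
# penalty replaced by a K-means objective alpha * ||F - M C'||^2, and the
# two-stage CCFE baseline that first fits plain MDFA and then picks the
# indeterminate score component to best match a K-means structure.

# Assign rows of F to the nearest centroid (squared Euclidean; ties go to
# the lowest-index centroid, which is what which.min does).
.assign_clusters <- function(F, C) {
  d2 <- outer(rowSums(F^2), rep(1, nrow(C))) -
    2 * tcrossprod(F, C) + outer(rep(1, nrow(F)), rowSums(C^2))
  apply(d2, 1, which.min)
}

.centroid_update <- function(F, cl, k) {
  C <- matrix(0, k, ncol(F))
  for (g in seq_len(k)) {
    idx <- cl == g
    if (any(idx)) C[g, ] <- colMeans(F[idx, , drop = FALSE])
  }
  C
}

# One K-means sweep on F given centroids C: assignment, empty-cluster
# re-seeding (empty centroid jumps to the point farthest from its current
# centroid), centroid update. Both sub-steps decrease ||F - M C'||^2.
.kmeans_step <- function(F, C) {
  k <- nrow(C)
  cl <- .assign_clusters(F, C)
  guard <- 0L
  while (length(unique(cl)) < k && guard < k) {
    empty <- setdiff(seq_len(k), unique(cl))
    d2 <- rowSums((F - C[cl, , drop = FALSE])^2)
    far <- which.max(d2)
    C[empty[1], ] <- F[far, ]
    cl <- .assign_clusters(F, C)
    guard <- guard + 1L
  }
  C <- .centroid_update(F, cl, k)
  list(cluster = cl, C = C)
}

.membership_matrix <- function(cl, k) {
  M <- matrix(0, length(cl), k)
  M[cbind(seq_along(cl), cl)] <- 1
  M
}

#' Fit clustering-based factor exploration (CFE)
#'
#' Minimizes `||X - F A' - U Psi||^2 + alpha ||F - M C'||^2` over the
#' factor-model parameters, the constrained scores, a binary membership
#' matrix `M` (rows sum to 1) and centroids `C`: the penalty is the
#' K-means objective applied to the common factor scores, so the scores
#' are estimated and clustered jointly. The score update reuses the RFE
#' block machinery with the criterion block replaced by the current
#' centroid targets `M C'` and its coefficient block fixed to the
#' identity; the clustering is updated by alternating nearest-centroid
#' assignment and centroid means. With a small `alpha` the clustering
#' plays a minimal role, so no artificial cluster structure is imposed on
#' scores that have none.
#'
#' @inheritParams fit_rfe
#' @param k Number of clusters (`2 <= k < n`; `k = 1` is allowed and
#'   reduces the penalty to shrinkage toward the score centroid).
#' @return An object of classes `cfe_fit`/`fe_fit` with the additional
#'   elements `cluster` (integer vector of 1-based memberships),
#'   `membership` (binary n x k matrix) and `centroids` (k x r matrix).
#' @examples
#' demo <- generate_clustered_demo(n = 90, r = 2, k = 3, separation = 4, seed = 5)
#' fit <- fit_cfe(demo$data, r = 2, k = 3, control = fe_control(n_starts = 5, seed = 5))
#' cluster_stats(fit)$min_within
#' @export
fit_cfe <- function(data, r, k, control = fe_control()) {
  d <- .as_fe_data(data)
  X <- d$X
  n <- nrow(X); p <- ncol(X)
  .check_fit_dims(n, p, NULL, r)
  if (k >= n) abort("`k` must be smaller than the number of observations.")
  if (k < 1) abort("`k` must be at least 1.")
  .rank_warn(X)
  alpha <- control$alpha

  runner <- function() {
    A <- .init_loadings(X, r)
    psi <- 0.5 * apply(X, 2, sd)
    # initial scores without the penalty, then seed centroids at k rows
    sv <- svd(X %*% cbind(A, diag(psi, p)))
    Z <- sqrt(n) * tcrossprod(sv$u, sv$v)
    Fm <- Z[, seq_len(r), drop = FALSE]
    C <- Fm[sample.int(n, k), , drop = FALSE]
    cl <- NULL
    repeat {  # K-means to convergence on the initial (un-penalized) scores
      km <- .kmeans_step(Fm, C)
      if (!is.null(cl) && all(km$cluster == cl) &&
          max(abs(km$C - C)) < 1e-12) break
      cl <- km$cluster; C <- km$C
    }
    denom <- sum(X^2)
    loss_prev <- Inf; path <- numeric(0)
    converged <- FALSE; rank_flag <- FALSE
    for (it in seq_len(control$max_iter)) {
      Tgt <- C[cl, , drop = FALSE]              # M C'
      G <- cbind(X, sqrt(alpha) * Tgt)
      W <- rbind(cbind(A, diag(psi, p)),
                 cbind(sqrt(alpha) * diag(r), matrix(0, r, p)))
      GW <- G %*% W
      sv <- svd(GW)
      if (sv$d[length(sv$d)] <= max(dim(GW)) * .Machine$double.eps * max(sv$d[1], 1)) {
        rank_flag <- TRUE
      }
      Z <- sqrt(n) * tcrossprod(sv$u, sv$v)
      Fm <- Z[, seq_len(r), drop = FALSE]
      U <- Z[, r + seq_len(p), drop = FALSE]
      psi <- pmax(colSums(U * X) / n, 0)
      A <- crossprod(X, Fm) / n
      km <- .kmeans_step(Fm, C)
      cl <- km$cluster; C <- km$C
      loss <- sum((X - tcrossprod(Fm, A) - sweep(U, 2, psi, `*`))^2) +
        alpha * sum((Fm - C[cl, , drop = FALSE])^2)
      path <- c(path, loss)
      if (loss > loss_prev + 1e-9 * max(1, loss_prev)) {
        abort(sprintf("Internal consistency failure: CFE loss increased from %.10g to %.10g.",
                      loss_prev, loss))
      }
      if (is.finite(loss_prev) && (loss_prev - loss) / denom < control$tol) {
        converged <- TRUE
        break
      }
      loss_prev <- loss
    }
    list(A = A, psi = psi, B = NULL, F = Fm, U = U, loss = loss, path = path,
         converged = converged, n_iter = length(path), rank_deficient = rank_flag,
         cluster = cl, C = C)
  }

  ms <- .multistart(runner, control)
  b <- ms$best
  .new_fit(ms, d, r, control, class = "cfe_fit",
           extra = list(cluster = b$cluster,
                        membership = .membership_matrix(b$cluster, k),
                        centroids = b$C, k = k))
}

#' Fit the two-stage CCFE baseline
#'
#' Clustered common factor exploration (CCFE) first fits plain MDFA, then
#' resolves the score indeterminacy *post hoc*: with the determinate score
#' part `F_det` and an indeterminate component ranging over orthonormal
#' frames orthogonal to `col(X)` (see [decompose_scores()]), it alternates
#' K-means steps on the current scores with a closed-form orthogonal
#' Procrustes update of the frame, minimizing `||F - M C'||^2`. Because
#' the indeterminate component is free to chase the centroids at no cost
#' to the factor-model fit, CCFE carves out sharply separated clusters
#' even when the underlying scores have none.
#'
#' @inheritParams fit_cfe
#' @param mdfa Optionally, an already fitted `mdfa_fit` for the same data
#'   (stage 1); when `NULL` it is fitted internally with `control`.
#' @return An object of classes `ccfe_fit`/`fe_fit` with cluster elements
#'   as in [fit_cfe()] plus `stage2_path` (the K-means objective per
#'   alternation of the best start). The reported `best_loss`/`loss_path`
#'   are the MDFA loss of stage 1, which stage 2 leaves unchanged.
#' @export
fit_ccfe <- function(data, r, k, control = fe_control(), mdfa = NULL) {
  d <- .as_fe_data(data)
  X <- d$X
  n <- nrow(X); p <- ncol(X)
  if (k >= n) abort("`k` must be smaller than the number of observations.")
  stage1 <- mdfa %||% fit_mdfa(d, r, control)
  stopifnot(inherits(stage1, "fe_fit"))
  dec <- decompose_scores(stage1, seed = control$seed)
  N <- t(dec$Q0[seq_len(r), , drop = FALSE])          # r x r right factor of the F block
  qr_x <- qr(X)
  F_det <- dec$F_det

  kmeans_converge <- function(Fm, C) {
    cl <- NULL
    repeat {
      km <- .kmeans_step(Fm, C)
      if (!is.null(cl) && all(km$cluster == cl) &&
          max(abs(km$C - C)) < 1e-12) break
      cl <- km$cluster; C <- km$C
    }
    list(cluster = cl, C = C)
  }

  run_stage2 <- function() {
    # Initial partition: K-means on the determinate part alone, so stage 2
    # starts from the cluster structure visible in the identified scores.
    km <- kmeans_converge(F_det, F_det[sample.int(n, k), , drop = FALSE])
    cl <- km$cluster; C <- km$C
    S <- dec$basis_perp
    Fm <- F_det + sqrt(n) * S %*% N
    obj_prev <- Inf; path <- numeric(0)
    for (it in seq_len(control$max_iter)) {
      # frame update: maximize tr(S' (I - P_X)(M C' - F_det) N') over
      # orthonormal S orthogonal to col(X)  ->  polar factor
      R <- C[cl, , drop = FALSE] - F_det
      Rp <- R %*% t(N)
      Rp <- Rp - qr.fitted(qr_x, Rp)
      sv <- svd(Rp)
      S <- tcrossprod(sv$u, sv$v)
      Fm <- F_det + sqrt(n) * S %*% N
      km <- kmeans_converge(Fm, C)
      cl <- km$cluster; C <- km$C
      obj <- sum((Fm - C[cl, , drop = FALSE])^2)
      path <- c(path, obj)
      if (obj > obj_prev + 1e-9 * max(1, obj_prev)) {
        abort(sprintf("Internal consistency failure: CCFE stage-2 objective increased from %.10g to %.10g.",
                      obj_prev, obj))
      }
      if (is.finite(obj_prev) && (obj_prev - obj) / max(1, sum(F_det^2)) < control$tol) break
      obj_prev <- obj
    }
    list(S = S, F = Fm, cluster = cl, C = C, obj = obj, path = path)
  }

  best <- NULL
  for (s in seq_len(control$n_starts)) {
    set.seed(control$seed + s)
    cand <- run_stage2()
    if (is.null(best) || cand$obj < best$obj) best <- cand
  }

  Z <- dec$Z_det + sqrt(n) * best$S %*% t(dec$Q0)
  scores <- fe_scores(Z[, seq_len(r), drop = FALSE], Z[, -seq_len(r), drop = FALSE])
  out <- stage1
  out$scores <- scores
  out$cluster <- best$cluster
  out$membership <- .membership_matrix(best$cluster, k)
  out$centroids <- best$C
  out$k <- k
  out$stage2_path <- best$path
  out$data <- d
  class(out) <- c("ccfe_fit", "fe_fit")
  out
}

#' Within-cluster variance and centroid separation of clustered scores
#'
#' Within-cluster variance of a cluster is the mean squared Euclidean
#' distance of its member scores to the cluster centroid; separation is
#' the Euclidean distance between centroid rows. The two summaries
#' `min_within` and `max_between` are the statistics used to contrast CFE
#' with CCFE on cluster-free data.
#'
#' @param x A `cfe_fit`/`ccfe_fit` object, or a numeric score matrix.
#' @param cluster Integer memberships (1-based), required when `x` is a
#'   matrix.
#' @param centroids Optional k x r centroid matrix; cluster means of the
#'   scores are used when omitted.
#' @param ... Unused.
#' @return A list with tibbles `within` (`cluster`, `size`,
#'   `within_variance`) and `between` (`cluster_a`, `cluster_b`,
#'   `distance`), plus scalars `min_within` and `max_between`.
#' @export
cluster_stats <- function(x, ...) UseMethod("cluster_stats")

#' @rdname cluster_stats
#' @export
cluster_stats.default <- function(x, cluster, centroids = NULL, ...) {
  F <- .as_numeric_matrix(x, "x")
  cluster <- as.integer(cluster)
  if (length(cluster) != nrow(F)) abort("`cluster` must have one entry per row of the score matrix.")
  k <- max(cluster)
  sizes <- tabulate(cluster, k)
  if (any(sizes == 0)) abort("Empty cluster: within-cluster variance is undefined.")
  if (is.null(centroids)) centroids <- .centroid_update(F, cluster, k)
  within <- vapply(seq_len(k), function(g) {
    idx <- cluster == g
    mean(rowSums((F[idx, , drop = FALSE] -
                    matrix(centroids[g, ], sum(idx), ncol(F), byrow = TRUE))^2))
  }, numeric(1))
  pairs <- utils::combn(k, 2)
  between <- tibble::tibble(
    cluster_a = pairs[1, ], cluster_b = pairs[2, ],
    distance = apply(pairs, 2, function(ij) {
      sqrt(sum((centroids[ij[1], ] - centroids[ij[2], ])^2))
    })
  )
  list(within = tibble::tibble(cluster = seq_len(k), size = sizes,
                               within_variance = within),
       between = between,
       min_within = min(within),
       max_between = max(between$distance))
}

#' @rdname cluster_stats
#' @export
cluster_stats.fe_fit <- function(x, ...) {
  if (is.null(x$cluster)) abort("This fit has no cluster structure; use fit_cfe() or fit_ccfe().")
  cluster_stats(x$scores$F, x$cluster, x$centroids)
}
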