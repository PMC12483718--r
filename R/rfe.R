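# Regression-based factor score exploration (RFE): joint alternating least
# squares over the loadings A, the uniqueness square roots psi, the
# criterion regression coefficients B, and the constrained score block
# Z = [F U]. Each update below is the exact conditional minimizer of the
# objective ||X - FA' - U Psi||^2 + alpha ||Y - FB'||^2, so the loss can
# never increase across a cycle.

#' Build the augmented data and weight blocks of the RFE objective
#'
#' Stacks the observed variables and the scaled criteria into
#' `G = [X, sqrt(alpha) Y]` and the parameters into the weight block
#' `W = rbind(cbind(A, Psi), cbind(sqrt(alpha) B, 0))`, so that the full
#' RFE objective equals the single Frobenius norm `||G - Z W'||^2`. This
#' identity is what reduces the score update to an orthogonal Procrustes
#' problem.
#'
#' @param data An [fe_data] bundle with external criteria `Y` (for plain
#'   MDFA pass a bundle without `Y`; the blocks then reduce to `X` and
#'   `[A, Psi]`).
#' @param params An [fe_params] object (with `B` when `Y` is present).
#' @param alpha Positive tuning parameter.
#' @return A list with matrices `G` (n x (p+q)) and `W` ((p+q) x (r+p)),
#'   and the dimensions `r`, `p` as attributes.
#' @export
build_blocks <- function(data, params, alpha) {
  d <- .as_fe_data(data)
  if (alpha <= 0) abort("`alpha` must be positive.")
  p <- ncol(d$X); r <- ncol(params$A)
  Psi_block <- diag(params$psi, p)
  if (is.null(d$Y)) {
    G <- d$X
    W <- cbind(params$A, Psi_block)
  } else {
    if (is.null(params$B)) abort("`params$B` is required when criteria are present.")
    q <- ncol(d$Y)
    G <- cbind(d$X, sqrt(alpha) * d$Y)
    W <- rbind(cbind(params$A, Psi_block),
               cbind(sqrt(alpha) * params$B, matrix(0, q, p)))
  }
  structure(list(G = G, W = W), r = r, p = p, class = "fe_blocks")
}

#' Constrained score update (ten Berge / orthogonal Procrustes)
#'
#' Given the blocks of [build_blocks()], finds the score block `Z = [F U]`
#' that minimizes `||G - Z W'||^2` subject to `(1/n) Z'Z = I`: with the
#' singular value decomposition `G W = P L Q'`, the maximizer of
#' `tr(W'G'Z)` is `Z = sqrt(n) P Q'`. The result satisfies the constraint
#' exactly (up to floating point). Uniqueness of the update requires `G W`
#' to have full column rank; rank deficiency is reported via the
#' `rank_deficient` attribute (and a warning), because then the scores are
#' not uniquely determined.
#'
#' @param blocks Result of [build_blocks()].
#' @param n Number of observations (rows of `G`).
#' @return An [fe_scores] object with attribute `rank_deficient`.
#' @export
update_scores <- function(blocks, n) {
  stopifnot(inherits(blocks, "fe_blocks"))
  r <- attr(blocks, "r"); p <- attr(blocks, "p")
  GW <- blocks$G %*% blocks$W
  sv <- svd(GW)
  deficient <- sv$d[length(sv$d)] <= max(dim(GW)) * .Machine$double.eps * max(sv$d[1], 1)
  if (deficient) {
    warn("The product G W is rank deficient: the score update is not unique.")
  }
  Z <- sqrt(n) * tcrossprod(sv$u, sv$v)
  out <- fe_scores(Z[, seq_len(r), drop = FALSE],
                   Z[, r + seq_len(p), drop = FALSE])
  attr(out, "rank_deficient") <- deficient
  out
}

#' Conditional update of the uniqueness square roots
#'
#' With the constraint in force (`U'U = n I`, `F'U = 0`), the diagonal
#' Psi minimizing the factor loss given the scores is
#' `psi_j = (1/n) u_j' x_j`. Values in `(-1e-10, 0)` are rounded to zero;
#' a genuinely negative value signals a broken iterate and is an error.
#'
#' @param data An [fe_data] bundle (or centered matrix).
#' @param scores An [fe_scores] object satisfying the constraint.
#' @return Numeric vector `psi` of length p.
#' @export
update_psi <- function(data, scores) {
  d <- .as_fe_data(data)
  psi <- colSums(scores$U * d$X) / nrow(d$X)
  if (any(psi < -1e-10)) {
    abort(sprintf("Negative uniqueness square root (min %.3e) at a supposedly valid iterate.",
                  min(psi)))
  }
  pmax(psi, 0)
}

#' Conditional update of loadings and regression coefficients
#'
#' With `F'F = n I` the unconstrained least squares minimizers given the
#' scores are `A = (1/n) X'F` and `B = (1/n) Y'F`.
#'
#' @inheritParams update_psi
#' @return A list with `A` (p x r) and `B` (q x r, `NULL` without criteria).
#' @export
update_coefficients <- function(data, scores) {
  d <- .as_fe_data(data)
  n <- nrow(d$X)
  list(A = crossprod(d$X, scores$F) / n,
       B = if (!is.null(d$Y)) crossprod(d$Y, scores$F) / n else NULL)
}

# PCA-based loading initialization: first r principal component loadings
# plus uniform noise so that independent starts explore distinct basins.
.init_loadings <- function(X, r) {
  n <- nrow(X)
  sv <- svd(X, nu = 0, nv = r)
  A <- sv$v[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)] / sqrt(n), r)
  A + matrix(runif(length(A), -0.25, 0.25), nrow(A))
}

.check_fit_dims <- function(n, p, q, r) {
  if (r < 1) abort("`r` must be at least 1.")
  if (r >= p) abort(sprintf("`r` (%d) must be smaller than the number of observed variables (%d).", r, p))
  if (n <= p + r) abort(sprintf("Need n > p + r (have n = %d, p + r = %d): the constrained score block cannot exist otherwise.", n, p + r))
  if (p >= n) abort("More variables than observations is not supported.")
  if (!is.null(q) && q > n) abort("More external criteria than observations is not supported.")
}

.rank_warn <- function(X) {
  rk <- qr(X)$rank
  if (rk < ncol(X)) {
    warn(sprintf("`x` is rank deficient (rank %d < %d variables); factor scores are not fully determined.",
                 rk, ncol(X)))
  }
  rk
}

# One full alternating fit from a single initialization. `target` and
# `coef_fixed` switch between MDFA (target NULL), RFE (target = Y, B free)
# and the CFE score step (target = MC', coefficient block fixed to I).
.als_run <- function(X, Y, r, alpha, tol, max_iter, psi_floor = 0) {
  n <- nrow(X); p <- ncol(X)
  A <- .init_loadings(X, r)
  psi <- 0.5 * apply(X, 2, sd)
  B <- if (!is.null(Y)) matrix(0, ncol(Y), r) else NULL
  denom <- sum(X^2) + if (!is.null(Y)) alpha * sum(Y^2) else 0
  loss_prev <- Inf
  path <- numeric(0)
  rank_flag <- FALSE
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- if (is.null(Y)) {
      cbind(A, diag(psi, p))
    } else {
      rbind(cbind(A, diag(psi, p)),
            cbind(sqrt(alpha) * B, matrix(0, ncol(Y), p)))
    }
    G <- if (is.null(Y)) X else cbind(X, sqrt(alpha) * Y)
    GW <- G %*% W
    sv <- svd(GW)
    if (sv$d[length(sv$d)] <= max(dim(GW)) * .Machine$double.eps * max(sv$d[1], 1)) {
      rank_flag <- TRUE
    }
    Z <- sqrt(n) * tcrossprod(sv$u, sv$v)
    Fm <- Z[, seq_len(r), drop = FALSE]
    U <- Z[, r + seq_len(p), drop = FALSE]
    psi <- pmax(colSums(U * X) / n, psi_floor)
    A <- crossprod(X, Fm) / n
    if (!is.null(Y)) B <- crossprod(Y, Fm) / n
    loss <- sum((X - tcrossprod(Fm, A) - sweep(U, 2, psi, `*`))^2)
    if (!is.null(Y)) loss <- loss + alpha * sum((Y - tcrossprod(Fm, B))^2)
    path <- c(path, loss)
    if (loss > loss_prev + 1e-9 * max(1, loss_prev)) {
      abort(sprintf("Internal consistency failure: loss increased from %.10g to %.10g.",
                    loss_prev, loss))
    }
    if (is.finite(loss_prev) && (loss_prev - loss) / denom < tol) {
      converged <- TRUE
      break
    }
    loss_prev <- loss
  }
  list(A = A, psi = psi, B = B, F = Fm, U = U, loss = loss, path = path,
       converged = converged, n_iter = length(path), rank_deficient = rank_flag)
}

.multistart <- function(runner, control) {
  runs <- vector("list", control$n_starts)
  for (s in seq_len(control$n_starts)) {
    set.seed(control$seed + s)
    runs[[s]] <- runner()
  }
  start_losses <- vapply(runs, `[[`, numeric(1), "loss")
  best <- which.min(start_losses)
  list(best = runs[[best]], start_losses = start_losses,
       local_prop = local_solution_proportion(start_losses, control$local_threshold))
}

#' Fit regression-based factor score exploration (RFE)
#'
#' Estimates the loadings `A`, the uniqueness square roots `psi`, the
#' criterion regression coefficients `B`, and uniquely determined common
#' and unique factor scores `F`, `U`, by alternating least squares on
#' `||X - F A' - U Psi||^2 + alpha ||Y - F B'||^2` under
#' `(1/n) [F U]'[F U] = I`. The penalty ties the common scores to the
#' external criteria, which removes the score indeterminacy of plain MDFA
#' whenever there are at least as many criteria as factors and the
#' relevant blocks have full rank.
#'
#' The algorithm is run from `control$n_starts` random initializations
#' (PCA loadings plus noise); the best converged solution is returned
#' together with every start's final loss and the proportion of starts
#' that ended in a worse (local) solution.
#'
#' @param data An [fe_data] bundle containing `x` and `y`, or a centered
#'   data frame / matrix of observed variables (then supply `y`).
#' @param r Number of common factors (at least 1, fewer than the number of
#'   observed variables).
#' @param y External criteria when `data` is not an [fe_data] bundle.
#' @param control An [fe_control] list: `alpha`, `n_starts`, `tol`,
#'   `max_iter`, `seed`, `local_threshold`.
#' @return An object of classes `rfe_fit`/`fe_fit`: a list with `params`
#'   ([fe_params]), `scores` ([fe_scores]), `loss_path`, `start_losses`,
#'   `best_loss`, `local_solution_proportion`, `alpha`, `converged`,
#'   `n_iter`, `rank_deficient`, and the data bundle used.
#' @examples
#' sim <- generate_dataset(simulation_design(n = 100, p = 6, q = 2, r = 2, seed = 3))
#' fit <- fit_rfe(sim$data, r = 2, control = fe_control(n_starts = 5, seed = 3))
#' glance(fit)
#' @seealso [fit_mdfa()], [fit_cfe()], [check_identification()]
#' @export
fit_rfe <- function(data, r, y = NULL, control = fe_control()) {
  d <- .as_fe_data(data, y, require_y = TRUE)
  X <- d$X; Y <- d$Y
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  .check_fit_dims(n, p, q, r)
  if (q < r) {
    warn(sprintf("Fewer criteria (q = %d) than factors (r = %d): factor scores are not guaranteed to be unique.", q, r))
  }
  .rank_warn(X)
  ms <- .multistart(function() .als_run(X, Y, r, control$alpha,
                                        control$tol, control$max_iter),
                    control)
  .new_fit(ms, d, r, control, class = "rfe_fit")
}

.new_fit <- function(ms, d, r, control, class, extra = list()) {
  b <- ms$best
  out <- c(list(
    params = fe_params(b$A, b$psi, b$B),
    scores = fe_scores(b$F, b$U),
    loss_path = b$path,
    start_losses = ms$start_losses,
    best_loss = min(ms$start_losses),
    local_solution_proportion = ms$local_prop,
    alpha = control$alpha,
    converged = b$converged,
    n_iter = b$n_iter,
    rank_deficient = b$rank_deficient,
    r = r,
    control = control,
    data = d
  ), extra)
  structure(out, class = c(class, "fe_fit"))
}

#' @export
print.fe_fit <- function(x, ...) {
  cat(sprintf("<%s: %d factor(s), n = %d, p = %d%s>\n",
              class(x)[1], x$r, nrow(x$data$X), ncol(x$data$X),
              if (!is.null(x$data$Y)) sprintf(", q = %d", ncol(x$data$Y)) else ""))
  cat(sprintf("  loss %.6g after %d iteration(s) (%s), alpha = %g\n",
              x$best_loss, x$n_iter,
              if (x$converged) "converged" else "iteration cap reached", x$alpha))
  cat(sprintf("  %d start(s), local-solution proportion %.3f\n",
              length(x$start_losses), x$local_solution_proportion))
  invisible(x)
}

#' Diagnose whether the fitted factor scores are uniquely determined
#'
#' Checks the rank and linear-independence conditions under which the
#' constrained score update has a unique solution, and measures how far the
#' fitted common scores are from the column space of the observed data
#' `[X, Y]` (they lie exactly inside it when the fit is identified, since
#' the scores are then a linear combination of the observed variables and
#' criteria).
#'
#' @param fit A fitted `rfe_fit` (or `mdfa_fit`, which is reported as
#'   non-unique).
#' @return A tibble with one row per condition: `condition`, `value`,
#'   `ok`.
#' @export
check_identification <- function(fit) {
  stopifnot(inherits(fit, "fe_fit"))
  d <- fit$data
  X <- d$X
  p <- ncol(X); r <- fit$r; n <- nrow(X)
  has_y <- !is.null(d$Y)
  q <- if (has_y) ncol(d$Y) else 0L

  rank_x <- qr(X)$rank
  rank_b <- if (has_y) qr(fit$params$B)$rank else 0L
  W <- if (has_y) {
    rbind(cbind(fit$params$A, diag(fit$params$psi, p)),
          cbind(sqrt(fit$alpha) * fit$params$B, matrix(0, q, p)))
  } else {
    cbind(fit$params$A, diag(fit$params$psi, p))
  }
  G <- if (has_y) cbind(X, sqrt(fit$alpha) * d$Y) else X
  sv <- svd(G %*% W, nu = 0, nv = 0)
  full_rank_gw <- sv$d[length(sv$d)] > max(n, r + p) * .Machine$double.eps * max(sv$d[1], 1)
  gaps <- if (length(sv$d) > 1) min(abs(diff(sv$d))) / max(sv$d[1], 1) else 1
  obs <- if (has_y) cbind(X, d$Y) else X
  qr_obs <- qr(obs)
  proj <- qr.fitted(qr_obs, fit$scores$F)
  resid_rel <- sqrt(sum((fit$scores$F - proj)^2)) / sqrt(sum(fit$scores$F^2))

  tibble::tibble(
    condition = c("criteria present (q >= 1)",
                  "at least as many criteria as factors (q >= r)",
                  "X has full column rank",
                  "B has full column rank",
                  "score-update product G W has full column rank",
                  "singular values of G W are distinct (relative min gap)",
                  "F lies in the column space of [X, Y] (relative residual)"),
    value = c(q, q - r, rank_x, rank_b,
              as.numeric(full_rank_gw), gaps, resid_rel),
    ok = c(q >= 1, q >= r, rank_x == p, has_y && rank_b == r,
           full_rank_gw, gaps > 1e-10, resid_rel < 1e-8)
  )
}
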