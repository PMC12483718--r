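# Tidier methods for fitted objects.

#' Tidy a fitted factor exploration model
#'
#' @param x A fitted `fe_fit` object.
#' @param matrix Which component to tidy: `"loadings"` (default; long
#'   tibble of variable, factor, loading, with the uniqueness repeated per
#'   variable), `"coefficients"` (criterion regression coefficients `B`),
#'   `"scores"` (common factor scores), `"unique_scores"`, or
#'   `"uniqueness"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fe_fit <- function(x, matrix = c("loadings", "coefficients", "scores",
                                      "unique_scores", "uniqueness"), ...) {
  matrix <- match.arg(matrix)
  fnames <- paste0("F", seq_len(x$r))
  d <- x$data
  long <- function(M, rows, row_col, cols) {
    dimnames(M) <- list(NULL, cols)
    tibble::as_tibble(M) |>
      dplyr::mutate("{row_col}" := rows, .before = 1) |>
      tidyr::pivot_longer(-1, names_to = "factor", values_to = "value")
  }
  switch(matrix,
    loadings = long(x$params$A, d$var_names_x, "variable", fnames) |>
      dplyr::rename(loading = "value") |>
      dplyr::left_join(tibble::tibble(variable = d$var_names_x,
                                      uniqueness = x$params$psi^2),
                       by = "variable"),
    coefficients = {
      if (is.null(x$params$B)) abort("This fit has no criterion coefficients.")
      long(x$params$B, d$var_names_y, "criterion", fnames) |>
        dplyr::rename(estimate = "value")
    },
    scores = long(x$scores$F, d$row_ids, "row_id", fnames) |>
      dplyr::rename(score = "value"),
    unique_scores = long(x$scores$U, d$row_ids, "row_id", d$var_names_x) |>
      dplyr::rename(variable = "factor", score = "value"),
    uniqueness = tibble::tibble(variable = d$var_names_x,
                                psi = x$params$psi,
                                uniqueness = x$params$psi^2)
  )
}

#' One-row model summary
#'
#' @param x A fitted `fe_fit` object.
#' @param ... Unused.
#' @return A tibble with dimensions, tuning parameter, loss, convergence
#'   and multi-start diagnostics.
#' @export
glance.fe_fit <- function(x, ...) {
  tibble::tibble(
    method = sub("_fit$", "", class(x)[1]),
    n = nrow(x$data$X), p = ncol(x$data$X),
    q = if (!is.null(x$data$Y)) ncol(x$data$Y) else 0L,
    r = x$r,
    k = x$k %||% NA_integer_,
    alpha = x$alpha,
    loss = x$best_loss,
    n_iter = x$n_iter,
    converged = x$converged,
    n_starts = length(x$start_losses),
    local_solution_proportion = x$local_solution_proportion
  )
}

#' Per-observation results
#'
#' @param x A fitted `fe_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per observation: `row_id`, the common
#'   factor scores `F1..Fr`, the model residual norm `.resid`, and the
#'   cluster membership `.cluster` for clustering fits.
#' @export
augment.fe_fit <- function(x, ...) {
  Fm <- x$scores$F
  dimnames(Fm) <- list(NULL, paste0("F", seq_len(x$r)))
  out <- dplyr::bind_cols(tibble::tibble(row_id = x$data$row_ids),
                          tibble::as_tibble(Fm))
  out$.resid <- individual_residuals(x)$residual
  if (!is.null(x$cluster)) out$.cluster <- factor(x$cluster)
  out
}
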