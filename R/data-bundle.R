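#' Assemble an analysis-ready data bundle
#'
#' Collects the observed-variable matrix `x` and (optionally) the
#' external-criteria matrix `y` into a validated bundle used by every
#' estimator in the package. The factor model is fitted to column-centered
#' matrices, so centering happens here, in the reader layer; the estimators
#' themselves refuse non-centered input rather than silently recentering.
#'
#' @param x A data frame or numeric matrix of observed variables, one row
#'   per observation (n) and one column per variable (p).
#' @param y Optional data frame or numeric matrix of external criteria
#'   (n x q), required by [fit_rfe()]. Default `NULL`.
#' @param center Column-center `x` (and `y`) before bundling. Default `TRUE`.
#'   Set to `FALSE` only when the input is already centered.
#' @param scale_y Additionally scale the columns of `y` to unit standard
#'   deviation. The criteria enter the fit through a squared-error penalty,
#'   so their scale matters; centering alone is the default convention.
#' @param drop_missing Drop rows with any missing cell (in `x` or `y`),
#'   with a message reporting the count. Default `TRUE`; with `FALSE`,
#'   missing values are an error.
#'
#' @return An object of class `fe_data`: a list with numeric matrices `X`
#'   (n x p) and `Y` (n x q or `NULL`), plus `row_ids`, `var_names_x`,
#'   `var_names_y`.
#'
#' @examples
#' d <- fe_data(swiss[, 1:4], y = swiss[, 5, drop = FALSE])
#' d
#' @export
fe_data <- function(x, y = NULL, center = TRUE, scale_y = FALSE,
                    drop_missing = TRUE) {
  X <- .as_numeric_matrix(x, "x")
  Y <- if (!is.null(y)) .as_numeric_matrix(y, "y") else NULL
  if (!is.null(Y) && nrow(Y) != nrow(X)) {
    abort(sprintf("`x` has %d rows but `y` has %d; they must describe the same observations.",
                  nrow(X), nrow(Y)))
  }
  row_ids <- rownames(X) %||% as.character(seq_len(nrow(X)))

  miss <- rowSums(is.na(X)) > 0
  if (!is.null(Y)) miss <- miss | rowSums(is.na(Y)) > 0
  if (any(miss)) {
    if (!drop_missing) abort("Missing values present; set `drop_missing = TRUE` or clean upstream.")
    inform(sprintf("Dropped %d row(s) with missing values.", sum(miss)))
    X <- X[!miss, , drop = FALSE]
    if (!is.null(Y)) Y <- Y[!miss, , drop = FALSE]
    row_ids <- row_ids[!miss]
  }
  if (nrow(X) < 2L) abort("At least two complete observations are required.")

  if (center) {
    X <- scale(X, center = TRUE, scale = FALSE)
    if (!is.null(Y)) Y <- scale(Y, center = TRUE, scale = scale_y)
  } else if (scale_y && !is.null(Y)) {
    Y <- scale(Y, center = FALSE, scale = apply(Y, 2, sd))
  }
  X <- .strip_scale_attrs(X)
  if (!is.null(Y)) Y <- .strip_scale_attrs(Y)

  out <- structure(
    list(X = X, Y = Y, row_ids = row_ids,
         var_names_x = colnames(X) %||% paste0("x", seq_len(ncol(X))),
         var_names_y = if (!is.null(Y)) colnames(Y) %||% paste0("y", seq_len(ncol(Y)))),
    class = "fe_data"
  )
  .validate_fe_data(out)
  out
}

.as_numeric_matrix <- function(m, arg) {
  if (is.data.frame(m)) {
    bad <- !vapply(m, is.numeric, logical(1))
    if (any(bad)) abort(sprintf("Non-numeric column(s) in `%s`: %s",
                                arg, paste(names(m)[bad], collapse = ", ")))
    m <- as.matrix(m)
  }
  if (!is.matrix(m) || !is.numeric(m)) abort(sprintf("`%s` must be a numeric matrix or data frame.", arg))
  storage.mode(m) <- "double"
  m
}

.strip_scale_attrs <- function(m) {
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  m
}

.validate_fe_data <- function(d, tol = 1e-8) {
  mx <- max(abs(colMeans(d$X)))
  if (mx > tol) {
    abort(sprintf(paste0("Columns of `x` are not centered (max |mean| = %.2e). ",
                         "Build inputs with fe_data(center = TRUE)."), mx))
  }
  if (!is.null(d$Y)) {
    my <- max(abs(colMeans(d$Y)))
    if (my > tol) {
      abort(sprintf("Columns of `y` are not centered (max |mean| = %.2e).", my))
    }
  }
  invisible(d)
}

# Accept either an fe_data bundle or raw tabular input; raw input must
# already be centered (estimators never recenter silently).
.as_fe_data <- function(data, y = NULL, require_y = FALSE, call_hint = "fe_data()") {
  if (inherits(data, "fe_data")) {
    d <- data
    if (!is.null(y)) abort("Supply `y` inside the fe_data bundle, not separately.")
  } else {
    d <- fe_data(data, y = y, center = FALSE, drop_missing = FALSE)
  }
  if (require_y && is.null(d$Y)) {
    abort(paste0("This estimator needs external criteria `y`; none were supplied. ",
                 "Use fit_mdfa() for factor analysis without criteria."))
  }
  d
}

#' @export
print.fe_data <- function(x, ...) {
  cat(sprintf("<fe_data: %d observations, %d observed variable(s)%s>\n",
              nrow(x$X), ncol(x$X),
              if (!is.null(x$Y)) sprintf(", %d external criteria", ncol(x$Y)) else ""))
  invisible(x)
}

#' @export
as.matrix.fe_data <- function(x, ...) x$X
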