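# Delimited-matrix input, artifact output, and the simulation driver.

#' Read a numeric matrix from a delimited text file
#'
#' Parses a CSV or TSV (the delimiter is sniffed from the first line),
#' optionally using a header row for variable names and a first column of
#' row identifiers. Rows containing any missing cell are dropped with a
#' message reporting the count; the matrix can be column-centered on the
#' way in, which is the form the estimators require.
#'
#' @param path File path.
#' @param has_header First row holds variable names. Default `TRUE`.
#' @param has_rownames First column holds row identifiers. Default `FALSE`.
#' @param center Column-center the matrix. Default `TRUE`.
#' @return A numeric matrix with `dimnames`; dropped-row count in
#'   attribute `n_dropped`.
#' @export
read_matrix <- function(path, has_header = TRUE, has_rownames = FALSE,
                        center = TRUE) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  tb <- readr::read_delim(path, delim = delim,
                          col_names = has_header,
                          show_col_types = FALSE, progress = FALSE)
  rn <- NULL
  if (has_rownames) {
    rn <- as.character(tb[[1]])
    tb <- tb[, -1, drop = FALSE]
  }
  bad <- !vapply(tb, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("Non-numeric column(s): %s", paste(names(tb)[bad], collapse = ", ")))
  }
  M <- as.matrix(tb)
  keep <- rowSums(is.na(M)) == 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d row(s) with missing values.", n_dropped))
    M <- M[keep, , drop = FALSE]
    if (!is.null(rn)) rn <- rn[keep]
  }
  if (center) M <- .strip_scale_attrs(scale(M, center = TRUE, scale = FALSE))
  rownames(M) <- rn
  attr(M, "n_dropped") <- n_dropped
  M
}

# Order factors by explained sum of squares of the loadings (descending)
# and fix signs so each loading column's largest-magnitude entry is
# positive; the same reordering is applied to scores and coefficients.
.canonicalize_fit <- function(fit) {
  A <- fit$params$A
  ord <- order(colSums(A^2), decreasing = TRUE)
  sgn <- vapply(ord, function(j) sign(A[which.max(abs(A[, j])), j]), numeric(1))
  sgn[sgn == 0] <- 1
  fit$params$A <- sweep(A[, ord, drop = FALSE], 2, sgn, `*`)
  if (!is.null(fit$params$B)) {
    fit$params$B <- sweep(fit$params$B[, ord, drop = FALSE], 2, sgn, `*`)
  }
  fit$scores$F <- sweep(fit$scores$F[, ord, drop = FALSE], 2, sgn, `*`)
  if (!is.null(fit$centroids)) {
    fit$centroids <- sweep(fit$centroids[, ord, drop = FALSE], 2, sgn, `*`)
  }
  fit
}

#' Fit a model and write all artifacts to a directory
#'
#' Thin driver over the `fit_*()` functions: reads nothing, fits the
#' requested model to an [fe_data] bundle, canonicalizes factor order and
#' signs (factors sorted by explained sum of squares, largest loading
#' positive), and writes loadings, uniquenesses, coefficients, scores,
#' cluster memberships, the loss trajectory, the multi-start summary and
#' a JSON run manifest.
#'
#' @param data An [fe_data] bundle.
#' @param method One of `"mdfa"`, `"rfe"`, `"cfe"`, `"ccfe"`.
#' @param r Number of factors.
#' @param out_dir Output directory (created if absent).
#' @param k Number of clusters (cfe/ccfe).
#' @param control An [fe_control] list.
#' @return The fitted object, invisibly; `status` attribute is 0 on a
#'   clean converged fit, 2 when warnings (rank deficiency, q < r,
#'   non-convergence) were raised.
#' @export
run_fit <- function(data, method = c("mdfa", "rfe", "cfe", "ccfe"), r,
                    out_dir, k = NULL, control = fe_control()) {
  method <- match.arg(method)
  d <- .as_fe_data(data, require_y = method == "rfe")
  if (method %in% c("cfe", "ccfe") && is.null(k)) {
    abort(sprintf("`k` is required for method '%s'.", method))
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    switch(method,
           mdfa = fit_mdfa(d, r, control),
           rfe  = fit_rfe(d, r, control = control),
           cfe  = fit_cfe(d, r, k, control),
           ccfe = fit_ccfe(d, r, k, control)),
    warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") },
    rlang_warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") }
  )
  fit <- .canonicalize_fit(fit)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fnames <- paste0("F", seq_len(r))
  A <- fit$params$A
  dimnames(A) <- list(NULL, fnames)
  lo <- tibble::as_tibble(A)
  lo <- dplyr::bind_cols(tibble::tibble(variable = d$var_names_x), lo)
  readr::write_csv(lo, file.path(out_dir, "loadings.csv"))
  readr::write_csv(tibble::tibble(variable = d$var_names_x,
                                  psi = fit$params$psi,
                                  uniqueness = fit$params$psi^2),
                   file.path(out_dir, "uniqueness.csv"))
  if (!is.null(fit$params$B)) {
    Bm <- fit$params$B; dimnames(Bm) <- list(NULL, fnames)
    readr::write_csv(dplyr::bind_cols(tibble::tibble(criterion = d$var_names_y),
                                      tibble::as_tibble(Bm)),
                     file.path(out_dir, "coefficients.csv"))
  }
  Fm <- fit$scores$F; dimnames(Fm) <- list(NULL, fnames)
  readr::write_csv(dplyr::bind_cols(tibble::tibble(row_id = d$row_ids),
                                    tibble::as_tibble(Fm)),
                   file.path(out_dir, "scores_common.csv"))
  Um <- fit$scores$U; dimnames(Um) <- list(NULL, paste0("U_", d$var_names_x))
  readr::write_csv(dplyr::bind_cols(tibble::tibble(row_id = d$row_ids),
                                    tibble::as_tibble(Um)),
                   file.path(out_dir, "scores_unique.csv"))
  if (!is.null(fit$cluster)) {
    readr::write_csv(tibble::tibble(row_id = d$row_ids, cluster = fit$cluster),
                     file.path(out_dir, "membership.csv"))
  }
  readr::write_csv(tibble::tibble(iteration = seq_along(fit$loss_path),
                                  loss = fit$loss_path),
                   file.path(out_dir, "loss_path.csv"))
  readr::write_csv(tibble::tibble(start = seq_along(fit$start_losses),
                                  loss = fit$start_losses),
                   file.path(out_dir, "starts.csv"))
  manifest <- list(method = method, r = r, k = k,
                   alpha = fit$alpha,
                   n_starts = fit$control$n_starts,
                   tol = fit$control$tol, max_iter = fit$control$max_iter,
                   seed = fit$control$seed,
                   converged = fit$converged,
                   best_loss = fit$best_loss,
                   local_solution_proportion = fit$local_solution_proportion,
                   package_version = as.character(utils::packageVersion("fsexplore")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  status <- if (warned || !fit$converged) 2L else 0L
  attr(fit, "status") <- status
  invisible(fit)
}

#' Run the parameter-recovery simulation study
#'
#' Loops over explained-variance conditions, replications and tuning
#' parameter values: each replication generates a fresh dataset from
#' [generate_dataset()], fits RFE, aligns the estimates to the generating
#' truth and scores them with [recovery_report()].
#'
#' @param rho_grid Explained-variance conditions. Default `c(0.5, 0.7, 0.9)`.
#' @param alpha_grid Tuning-parameter values fitted to every dataset.
#'   Default `c(0.01, 0.05, 0.1, 0.5, 1, 5)`.
#' @param n_reps Replications per condition (100 in the full design; use
#'   fewer for desk-scale runs).
#' @param design_base An [simulation_design()] giving dimensions; its
#'   `rho` and `seed` are overridden per cell.
#' @param control An [fe_control] for the fits (its `alpha` is overridden
#'   by `alpha_grid`).
#' @param seed Master seed; replication `i` of condition `c` derives its
#'   own dataset seed from it.
#' @return A tibble with one row per condition x replication x alpha:
#'   the five RMSEA columns, the local-solution proportion, and the seeds
#'   used.
#' @export
run_simulation <- function(rho_grid = c(0.5, 0.7, 0.9),
                           alpha_grid = c(0.01, 0.05, 0.1, 0.5, 1, 5),
                           n_reps = 20,
                           design_base = simulation_design(),
                           control = fe_control(),
                           seed = 1) {
  cells <- tidyr::expand_grid(rho = rho_grid, rep = seq_len(n_reps))
  purrr::pmap_dfr(cells, function(rho, rep) {
    ds_seed <- seed + 7919L * match(rho, rho_grid) + 131L * rep
    design <- design_base
    design$rho <- rho
    design$seed <- ds_seed
    sim <- generate_dataset(design)
    purrr::map_dfr(alpha_grid, function(a) {
      ctrl <- control
      ctrl$alpha <- a
      ctrl$seed <- ds_seed + 1L
      fit <- fit_rfe(sim$data, design$r, control = ctrl)
      rep_row <- recovery_report(fit, sim$truth)
      dplyr::bind_cols(tibble::tibble(rho = rho, replication = rep,
                                      alpha = a, seed = ds_seed), rep_row)
    })
  })
}
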