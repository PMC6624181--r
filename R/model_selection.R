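# run expr with a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Choose the ridge penalties by k-fold cross-validation
#'
#' Evaluates every `(lambda_G, lambda_P)` cell of a two-dimensional grid by
#' k-fold cross-validation: the model is fitted on k-1 folds and the
#' unpenalized quasi-deviance of the held-out fold's predictions is
#' accumulated. Standardization of the collapsed design is recomputed on
#' each training fold and applied to the held-out fold, so no holdout
#' information leaks into the fit. Ties are broken toward the larger
#' (more regularized) penalty pair.
#'
#' @param design a `pharaoh_design` (its unstandardized burdens are used
#'   for fold-wise restandardization).
#' @param Y N x Q phenotype matrix.
#' @param lambda_G_values,lambda_P_values ascending positive penalty grids.
#' @param k_folds number of folds (default 5).
#' @param fold_seed seed for the fold assignment.
#' @param family,corstr passed to [pharaoh_gee()].
#' @param ... further arguments to [pharaoh_gee()].
#' @return an object of class `pharaoh_cv`: list with `lambda_G`,
#'   `lambda_P`, `cv_table` (data frame of grid cells and accumulated
#'   holdout quasi-deviance; `NA` for cells whose fit failed), `k_folds`,
#'   `fold_seed`, `folds`.
#' @export
pharaoh_cv <- function(design, Y,
                       lambda_G_values = c(0.01, 0.1, 1, 10, 100),
                       lambda_P_values = c(0.01, 0.1, 1, 10, 100),
                       k_folds = 5, fold_seed = 1,
                       family = "gaussian", corstr = "independence", ...) {
  stopifnot(inherits(design, "pharaoh_design"), k_folds >= 2,
            all(lambda_G_values > 0), all(lambda_P_values > 0))
  Y <- as_phenotype_matrix(Y)
  N <- design$N
  if (N < k_folds) stop("need at least k_folds samples")
  folds <- with_seed(fold_seed,
                     sample(rep_len(seq_len(k_folds), N)))
  grid <- expand.grid(lambda_G = sort(lambda_G_values),
                      lambda_P = sort(lambda_P_values))
  qd <- rep(NA_real_, nrow(grid))
  cv_fold <- function(tr, lg, lp) {
    dtr <- standardize_design(design$X_raw[tr, , drop = FALSE],
                              block = design$block,
                              pathways = design$pathways)
    fit <- pharaoh_gee(dtr, Y[tr, , drop = FALSE], family = family,
                       lambda_G = lg, lambda_P = lp, corstr = corstr, ...)
    # held-out design standardized with training statistics only;
    # a training fold may have dropped zero-variance columns
    keep <- match(paste(dtr$block$pathway, dtr$block$gene),
                  paste(design$block$pathway, design$block$gene))
    Xh_raw <- design$X_raw[!tr, c(1L, keep + 1L), drop = FALSE]
    Xh <- apply_standardization(Xh_raw, dtr$center, dtr$scale)
    mu <- linkinv_fun(component_scores(Xh, fit$W) %*% fit$B, family)
    quasi_deviance(Y[!tr, , drop = FALSE], mu, family)
  }
  for (g in seq_len(nrow(grid))) {
    total <- 0; ok <- TRUE
    for (f in seq_len(k_folds)) {
      res <- tryCatch(
        suppressWarnings(cv_fold(folds != f, grid$lambda_G[g],
                                 grid$lambda_P[g])),
        error = function(e) NA_real_)
      if (is.na(res)) { ok <- FALSE; break }
      total <- total + res
    }
    if (ok) qd[g] <- total
  }
  if (all(is.na(qd))) stop("cross-validation failed in every grid cell")
  grid$quasi_deviance <- qd
  best <- which(qd == min(qd, na.rm = TRUE))
  # ties toward more regularization: the grid is sorted ascending, so the
  # last tied cell has the largest (lambda_P, lambda_G)
  best <- best[length(best)]
  structure(list(lambda_G = grid$lambda_G[best],
                 lambda_P = grid$lambda_P[best],
                 cv_table = grid, k_folds = k_folds, fold_seed = fold_seed,
                 folds = folds),
            class = "pharaoh_cv")
}

#' @exportS3Method base::print
print.pharaoh_cv <- function(x, ...) {
  cat("k-fold CV over", nrow(x$cv_table), "penalty cells (k =",
      x$k_folds, ")\n")
  cat("  selected lambda_G =", x$lambda_G, ", lambda_P =", x$lambda_P, "\n")
  invisible(x)
}
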