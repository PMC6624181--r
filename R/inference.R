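#' Wald-type statistic for a pathway's joint effect
#'
#' `T = beta' cov^-1 beta`, testing all Q coefficients of one pathway
#' jointly against zero. If the covariance is singular, the Moore-Penrose
#' pseudo-inverse is used with a warning.
#'
#' @param beta length-Q coefficient vector of one pathway.
#' @param cov_beta Q x Q covariance matrix of those coefficients.
#' @return non-negative scalar statistic.
#' @export
wald_statistic <- function(beta, cov_beta) {
  beta <- as.numeric(beta)
  cov_beta <- as.matrix(cov_beta)
  stopifnot(length(beta) == nrow(cov_beta),
            nrow(cov_beta) == ncol(cov_beta))
  out <- tryCatch(drop(crossprod(beta, solve(cov_beta, beta))),
                  error = function(e) NA_real_)
  if (is.na(out) || out < 0) {
    warning("covariance not invertible/PSD; using pseudo-inverse")
    out <- drop(crossprod(beta, MASS::ginv(cov_beta) %*% beta))
    out <- max(out, 0)
  }
  out
}

#' Permutation ("indirect") covariance of pathway coefficients
#'
#' Sample covariance (denominator n_perm - 1) of a pathway's coefficient
#' vectors across permutation refits, used in the Wald-type statistic in
#' place of the direct sandwich estimator.
#'
#' @param null_betas n_perm x Q matrix of permuted coefficient vectors.
#' @return Q x Q covariance matrix.
#' @export
permutation_covariance <- function(null_betas) {
  null_betas <- as.matrix(null_betas)
  if (nrow(null_betas) < ncol(null_betas) + 2)
    stop("need at least Q + 2 permutations for a usable covariance")
  stats::cov(null_betas)
}

#' Direct (sandwich) covariance of the pathway coefficients
#'
#' Assembles the penalized-GEE sandwich on the component design:
#' bread `H + nE = sum_i Q_i' V_i^-1 Q_i + lambda_P D` (the coefficient
#' update's left-hand side, `D` zero on the intercept rows), meat
#' `M = sum_i Q_i' V_i^-1 (y_i - mu_i)(y_i - mu_i)' V_i^-1 Q_i`, and
#' `cov = (H + nE)^-1 M (H + nE)^-1`. With no penalty, gaussian responses,
#' independence working correlation and one phenotype this is the
#' classical GEE sandwich for the regression of y on the component scores.
#'
#' @param fit a converged [pharaoh_gee()] object.
#' @return an object of class `sandwich_parts`: list with `H`, `E`, `M`,
#'   `cov` (full `(K+1)Q` covariance, pathway-major order) and
#'   `cov_pathway` (list of per-pathway Q x Q blocks).
#' @export
sandwich_covariance <- function(fit) {
  stopifnot(inherits(fit, "pharaoh_gee"))
  Y <- fit$Y; Q <- ncol(Y); K <- fit$design$K
  Fm <- fit$F
  mu <- fit$fitted
  a <- sqrt(variance_function(mu, fit$family))
  Rinv <- solve(fit$alpha$R)
  phi <- fit$phi
  # bread: the B-update system. For gaussian dhalf = 1; binomial uses the
  # IRLS weight (see working_parts), matching the update equations.
  dhalf <- if (fit$family == "gaussian") matrix(1, nrow(Y), Q) else 1 / a
  H <- bsys_cpp(Fm, Y, dhalf, Rinv, phi)$LHS
  D <- rep(1, (K + 1) * Q); D[seq_len(Q)] <- 0
  E <- fit$lambda_P * diag(D)
  # meat: outer product of the per-cluster scores
  # s_i = Q_i' A^{1/2} R^-1 A^{-1/2} (y_i - mu_i) / phi, the estimating
  # function whose bread is H (reduces to Q_i' R^-1 e_i for gaussian)
  P <- K + 1
  Es <- (((Y - mu) / a) %*% Rinv) * a / phi
  U <- matrix(0, nrow(Y), P * Q)
  for (j in seq_len(P))
    U[, (j - 1) * Q + seq_len(Q)] <- Fm[, j] * Es
  M <- crossprod(U)
  bread_inv <- solve(H + E)
  cov_full <- bread_inv %*% M %*% bread_inv
  cov_full <- (cov_full + t(cov_full)) / 2
  cov_pathway <- lapply(seq_len(K), function(k)
    cov_full[k * Q + seq_len(Q), k * Q + seq_len(Q), drop = FALSE])
  names(cov_pathway) <- fit$design$pathways
  structure(list(H = H, E = E, M = M, cov = cov_full,
                 cov_pathway = cov_pathway),
            class = "sandwich_parts")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (`stats::p.adjust(p, "BH")`):
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "BH")
}

#' Westfall-Young max-T adjusted p-values
#'
#' Single-step max-T adjustment from joint permutation null statistics:
#' `adj_p_k = (1 + #\{perm : max_k' T_null >= T_obs_k\}) / (n_perm + 1)`.
#' With a single hypothesis this reduces to the raw permutation p-value;
#' in general it dominates it, accounting for the correlation between
#' pathway statistics.
#'
#' @param null_T n_perm x K matrix of permutation statistics (columns =
#'   pathways, from the same permutations).
#' @param T_obs length-K vector of observed statistics.
#' @return length-K vector of adjusted p-values.
#' @export
westfall_young <- function(null_T, T_obs) {
  null_T <- as.matrix(null_T)
  stopifnot(ncol(null_T) == length(T_obs))
  max_null <- apply(null_T, 1, max)
  vapply(T_obs, function(t) (1 + sum(max_null >= t)) / (nrow(null_T) + 1),
         numeric(1))
}

#' Permutation test of joint pathway (and gene) effects
#'
#' Refits the penalized GEE model under `n_perm` permutations of the
#' phenotype rows (whole Q-vectors are permuted across individuals,
#' preserving the within-cluster correlation under the null) with the
#' penalties held fixed, builds the empirical null distribution of the
#' pathway coefficient vectors and gene weights, and tests each pathway
#' with the Wald-type statistic using the permutation covariance (or the
#' sandwich covariance on request). p-values use the add-one rule
#' `p = (1 + #\{T_null >= T_obs\}) / (n_perm + 1)`; gene p-values are
#' two-sided on the weight against its permutation null. BH q-values and
#' Westfall-Young max-T adjusted p-values are attached.
#'
#' @param design a `pharaoh_design`.
#' @param Y N x Q phenotype matrix.
#' @param lambda_G,lambda_P ridge penalties (held fixed across
#'   permutations).
#' @param family,corstr passed to [pharaoh_gee()].
#' @param n_perm number of permutations (default 1000; a warning is
#'   issued below 1000, an error below 100 unless `force = TRUE`).
#' @param seed RNG seed for the permutations.
#' @param cov_method `"permutation"` (default) or `"sandwich"`.
#' @param force allow fewer than 100 permutations (testing only).
#' @param ... further arguments to [pharaoh_gee()].
#' @return an object of class `pharaoh_perm_test`: list with `pathways`
#'   (data frame: pathway, T, p, q, wy_p, per-phenotype beta), `genes`
#'   (data frame: gene, pathway, w, p, q), `null_T`, `null_betas`
#'   (n_perm x K x Q array), `null_weights`, `fit` (observed fit), `seed`,
#'   `n_perm`.
#' @export
pharaoh_perm_test <- function(design, Y, lambda_G = 1, lambda_P = 1,
                              family = "gaussian", corstr = "independence",
                              n_perm = 1000, seed = 1,
                              cov_method = c("permutation", "sandwich"),
                              force = FALSE, ...) {
  cov_method <- match.arg(cov_method)
  Y <- as_phenotype_matrix(Y)
  if (n_perm < 100 && !force) stop("n_perm must be at least 100")
  if (n_perm < 1000) warning("fewer than 1000 permutations; p-value ",
                             "resolution is limited", call. = FALSE)
  K <- design$K; Q <- ncol(Y); N <- design$N
  fit <- pharaoh_gee(design, Y, family = family, lambda_G = lambda_G,
                     lambda_P = lambda_P, corstr = corstr, ...)
  null_betas <- array(NA_real_, c(n_perm, K, Q))
  null_weights <- matrix(NA_real_, n_perm, length(fit$w))
  failures <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(N)
      pf <- tryCatch(
        suppressWarnings(
          pharaoh_gee(design, Y[idx, , drop = FALSE], family = family,
                      lambda_G = lambda_G, lambda_P = lambda_P,
                      corstr = corstr, ...)),
        error = function(e) NULL)
      if (is.null(pf)) { failures <- failures + 1L; next }
      null_betas[b, , ] <- pf$B[-1, , drop = FALSE]
      null_weights[b, ] <- pf$w
    }
  })
  if (failures > 0.05 * n_perm)
    stop("permutation fits failed in ", failures, "/", n_perm,
         " permutations; check penalties and data")
  ok <- !is.na(null_betas[, 1, 1])
  n_eff <- sum(ok)

  cov_k <- if (cov_method == "permutation") {
    lapply(seq_len(K), function(k)
      permutation_covariance(matrix(null_betas[ok, k, ], ncol = Q)))
  } else {
    sandwich_covariance(fit)$cov_pathway
  }
  T_obs <- vapply(seq_len(K), function(k)
    wald_statistic(fit$B[k + 1, ], cov_k[[k]]), numeric(1))
  null_T <- matrix(NA_real_, n_eff, K)
  for (k in seq_len(K)) {
    nb <- matrix(null_betas[ok, k, ], ncol = Q)
    null_T[, k] <- vapply(seq_len(n_eff), function(b)
      wald_statistic(nb[b, ], cov_k[[k]]), numeric(1))
  }
  p <- vapply(seq_len(K), function(k)
    (1 + sum(null_T[, k] >= T_obs[k])) / (n_eff + 1), numeric(1))
  q <- bh_fdr(p)
  wy <- westfall_young(null_T, T_obs)

  gw <- fit$w
  gp <- vapply(seq_along(gw), function(t)
    (1 + sum(abs(null_weights[ok, t]) >= abs(gw[t]))) / (n_eff + 1),
    numeric(1))
  gq <- bh_fdr(gp)

  beta_df <- as.data.frame(fit$B[-1, , drop = FALSE])
  names(beta_df) <- paste0("beta_", colnames(fit$B))
  pathways <- data.frame(pathway = design$pathways, T = T_obs, p = p,
                         q = q, wy_p = wy, beta_df,
                         row.names = NULL, stringsAsFactors = FALSE)
  genes <- data.frame(gene = design$block$gene,
                      pathway = design$block$pathway,
                      w = unname(gw), p = gp, q = gq,
                      stringsAsFactors = FALSE)
  structure(list(pathways = pathways, genes = genes, null_T = null_T,
                 null_betas = null_betas[ok, , , drop = FALSE],
                 null_weights = null_weights[ok, , drop = FALSE],
                 fit = fit, cov_pathway = cov_k, seed = seed,
                 n_perm = n_eff, failures = failures),
            class = "pharaoh_perm_test")
}

#' @exportS3Method base::print
print.pharaoh_perm_test <- function(x, digits = 6, ...) {
  cat("Permutation pathway test (", x$n_perm, " permutations)\n", sep = "")
  tab <- x$pathways
  tab$T <- signif(tab$T, digits); tab$p <- signif(tab$p, digits)
  tab$q <- signif(tab$q, digits); tab$wy_p <- signif(tab$wy_p, digits)
  print(tab[, c("pathway", "T", "p", "q", "wy_p")], row.names = FALSE)
  invisible(x)
}
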