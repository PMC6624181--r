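#' Component scores
#'
#' `F = X W`: the latent pathway component scores. Column 1 of the result is
#' identically 1 (the intercept pseudo-component).
#'
#' @param X N x (T+1) design matrix (intercept first).
#' @param W (T+1) x (K+1) block-structured weight matrix, `W[1,1] = 1`.
#' @return N x (K+1) matrix of component scores.
#' @export
component_scores <- function(X, W) {
  X <- as.matrix(X); W <- as.matrix(W)
  if (ncol(X) != nrow(W)) stop("non-conforming X and W")
  X %*% W
}

# full (T+1) x (K+1) weight matrix from the length-T free vector
expand_weights <- function(w, map, K) {
  T_all <- length(w)
  W <- matrix(0, T_all + 1L, K + 1L)
  W[1, 1] <- 1
  W[cbind(seq_len(T_all) + 1L, map + 1L)] <- w
  W
}

# fast component scores from the free weights
comp_scores_free <- function(X, w, map, K) {
  Wm <- matrix(0, length(w), K)
  Wm[cbind(seq_along(w), map)] <- w
  cbind(1, X[, -1, drop = FALSE] %*% Wm)
}

#' Working covariance of one cluster
#'
#' `Sigma_i = phi * A^{1/2} R A^{1/2}` with `A = diag(nu(mu))`, the marginal
#' covariance implied by the working correlation `R`.
#'
#' @param mu length-Q mean vector of one cluster.
#' @param R Q x Q working correlation matrix.
#' @param family `"gaussian"` or `"binomial"`.
#' @param phi dispersion.
#' @return Q x Q covariance matrix.
#' @export
working_covariance <- function(mu, R, family = "gaussian", phi = 1) {
  family <- check_family(family)
  mu <- clamp_mu(mu, family, warn = TRUE)
  a <- sqrt(variance_function(mu, family))
  phi * (R * tcrossprod(a))
}

#' Pearson residuals
#'
#' `r_ij = (y_ij - mu_ij) / sqrt(nu(mu_ij))`.
#'
#' @param Y,mu N x Q matrices of responses and fitted means.
#' @param family `"gaussian"` or `"binomial"`.
#' @return N x Q matrix of Pearson residuals.
#' @export
pearson_residuals <- function(Y, mu, family = "gaussian") {
  family <- check_family(family)
  Y <- as.matrix(Y); mu <- as.matrix(mu)
  stopifnot(all(dim(Y) == dim(mu)))
  mu <- clamp_mu(mu, family)
  (Y - mu) / sqrt(variance_function(mu, family))
}

#' Moment estimate of the dispersion
#'
#' `phi = sum(r^2) / (N Q - (K + sum(Tk)))`, the Pearson residual sum of
#' squares over the residual degrees of freedom of the structural model.
#'
#' @param residuals N x Q matrix of Pearson residuals.
#' @param K number of pathways.
#' @param Tk integer vector of genes per pathway.
#' @return scalar dispersion estimate.
#' @export
estimate_dispersion <- function(residuals, K, Tk) {
  residuals <- as.matrix(residuals)
  df <- nrow(residuals) * ncol(residuals) - (K + sum(Tk))
  if (df <= 0)
    stop("non-positive residual degrees of freedom: N*Q must exceed K + sum(Tk)")
  sum(residuals^2) / df
}

#' Moment estimate of the working correlation
#'
#' Updates `R(alpha)` from Pearson residuals: exchangeable uses the mean
#' within-cluster cross-product over pairs, AR-1 the mean lag-1 product,
#' unstructured the per-pair means (symmetrized, unit diagonal, eigenvalue
#' floor at 1e-6 then rescaled if not positive definite).
#'
#' @param residuals N x Q Pearson residual matrix.
#' @param phi dispersion.
#' @param structure one of `"independence"`, `"exchangeable"`, `"ar1"`,
#'   `"unstructured"`.
#' @return list with `structure`, `alpha` (parameter vector) and `R`
#'   (Q x Q working correlation).
#' @export
estimate_alpha <- function(residuals, phi = 1,
                           structure = c("independence", "exchangeable",
                                         "ar1", "unstructured")) {
  structure <- match.arg(structure)
  r <- unname(as.matrix(residuals))
  Q <- ncol(r); N <- nrow(r)
  cap <- 0.99
  if (Q == 1 || structure == "independence")
    return(list(structure = structure, alpha = numeric(0), R = diag(Q)))
  if (structure == "exchangeable") {
    cp <- crossprod(r) / (N * phi)          # mean_i r_ij r_ik / phi
    a <- mean(cp[upper.tri(cp)])
    a <- min(max(a, -1 / (Q - 1) + 1e-6), cap)
    R <- matrix(a, Q, Q); diag(R) <- 1
    return(list(structure = structure, alpha = a, R = R))
  }
  if (structure == "ar1") {
    a <- mean(r[, -Q, drop = FALSE] * r[, -1, drop = FALSE]) / phi
    a <- min(max(a, -cap), cap)
    R <- a^abs(outer(seq_len(Q), seq_len(Q), "-"))
    return(list(structure = structure, alpha = a, R = R))
  }
  # unstructured
  R <- crossprod(r) / (N * phi)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  off <- row(R) != col(R)
  R[off] <- pmin(pmax(R[off], -cap), cap)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    warning("unstructured working correlation not positive definite; ",
            "eigenvalue floor applied")
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
  }
  list(structure = structure, alpha = R[upper.tri(R)], R = R)
}

# GEE working quantities for the current linear predictor.
# For the update systems the cluster weight matrix is
#   diag(1/dhalf) Rinv diag(1/dhalf) / phi,
# the Fisher-scoring (IRLS) weight: dhalf = 1 for gaussian/identity and
# dhalf = 1/sqrt(nu(mu)) for binomial/logit, paired with the working
# response z = eta + (y - mu) g'(mu).
working_parts <- function(Y, eta, family) {
  if (family == "gaussian") {
    list(mu = eta, z = Y, dhalf = matrix(1, nrow(Y), ncol(Y)))
  } else {
    mu <- clamp_mu(plogis(eta), "binomial")
    nu <- mu * (1 - mu)
    list(mu = mu, z = eta + (Y - mu) / nu, dhalf = 1 / sqrt(nu))
  }
}

#' One ridge-GLS update of the pathway coefficients B
#'
#' Solves `(sum_i Q_i' V_i^-1 Q_i + lambda_P D) b = sum_i Q_i' V_i^-1 z_i`
#' with `Q_i = f_i' (x) I_Q`, where `z` is the GEE working response
#' (`z = y` for gaussian/identity) and `D` the penalty indicator (intercept
#' row unpenalized by default).
#'
#' @param design a `pharaoh_design`.
#' @param w length-T free weight vector.
#' @param B current (K+1) x Q coefficient matrix (used to form the working
#'   response for the binomial family; may be the initialization).
#' @param Y N x Q response matrix.
#' @param family,R,phi response family, Q x Q working correlation, dispersion.
#' @param lambda_P ridge penalty on the coefficients.
#' @param penalize_intercept logical; default FALSE.
#' @return updated (K+1) x Q coefficient matrix.
#' @export
update_B <- function(design, w, B, Y, family = "gaussian", R = NULL,
                     phi = 1, lambda_P = 0, penalize_intercept = FALSE) {
  family <- check_family(family)
  Y <- as_phenotype_matrix(Y)
  if (is.null(R)) R <- diag(ncol(Y))
  Fm <- comp_scores_free(design$X, w, design$block$k, design$K)
  update_B_core(Fm, B, Y, family, solve(R), phi, lambda_P,
                penalize_intercept)
}

update_B_core <- function(Fm, B, Y, family, Rinv, phi, lambda_P,
                          penalize_intercept = FALSE) {
  Q <- ncol(Y); P <- ncol(Fm)
  wp <- working_parts(Y, Fm %*% B, family)
  sys <- bsys_cpp(Fm, wp$z, wp$dhalf, Rinv, phi)
  D <- rep(1, P * Q)
  if (!penalize_intercept) D[seq_len(Q)] <- 0
  LHS <- sys$LHS + lambda_P * diag(D)
  b <- tryCatch(solve(LHS, sys$RHS), error = function(e)
    stop("singular coefficient system; set lambda_P > 0 for collinear components"))
  matrix(b, nrow = P, ncol = Q, byrow = TRUE, dimnames = dimnames(B))
}

#' One ridge-GLS update of the gene weights W
#'
#' Solves `(sum_i M_i' V_i^-1 M_i + lambda_G I) w = sum_i M_i' V_i^-1
#' (z_i - beta_0)` where `M_i` holds the columns of `x_i' (x) B'` for the
#' free (structurally nonzero) weights; the intercept contribution enters
#' as an offset. Structural zeros of W are preserved exactly.
#'
#' @inheritParams update_B
#' @param lambda_G ridge penalty on the weights.
#' @return updated length-T free weight vector.
#' @export
update_W <- function(design, w, B, Y, family = "gaussian", R = NULL,
                     phi = 1, lambda_G = 0) {
  family <- check_family(family)
  Y <- as_phenotype_matrix(Y)
  if (is.null(R)) R <- diag(ncol(Y))
  Fm <- comp_scores_free(design$X, w, design$block$k, design$K)
  update_W_core(design, Fm, B, Y, family, solve(R), phi, lambda_G)
}

update_W_core <- function(design, Fm, B, Y, family, Rinv, phi, lambda_G) {
  Q <- ncol(Y)
  wp <- working_parts(Y, Fm %*% B, family)
  Zr <- wp$z - matrix(B[1, ], nrow(Y), Q, byrow = TRUE)
  sys <- wsys_cpp(design$X[, -1, drop = FALSE], B[-1, , drop = FALSE],
                  as.integer(design$block$k) - 1L, Zr, wp$dhalf,
                  Rinv, phi)
  LHS <- sys$LHS + lambda_G * diag(nrow(design$block))
  tryCatch(drop(solve(LHS, sys$RHS)), error = function(e)
    stop("singular weight system; set lambda_G > 0 for collinear genes"))
}

#' Quasi-deviance of predictions
#'
#' Gaussian: `sum((y - mu)^2)`. Binomial: `2 sum(y log(y/mu) +
#' (1-y) log((1-y)/(1-mu)))` with the convention `0 log 0 = 0`.
#'
#' @param Y observed responses (vector or matrix).
#' @param mu predicted means (same shape).
#' @param family `"gaussian"` or `"binomial"`.
#' @return scalar quasi-deviance.
#' @export
quasi_deviance <- function(Y, mu, family = "gaussian") {
  family <- check_family(family)
  Y <- as.matrix(Y); mu <- as.matrix(mu)
  stopifnot(all(dim(Y) == dim(mu)))
  if (family == "gaussian") return(sum((Y - mu)^2))
  mu <- clamp_mu(mu, family)
  xlogy <- function(x, v) {          # x * log(v) with 0 * log(0) = 0
    out <- x * log(v)
    out[x == 0] <- 0
    out
  }
  2 * sum(xlogy(Y, Y / mu) + xlogy(1 - Y, (1 - Y) / (1 - mu)))
}

#' Fit the doubly ridge-penalized GEE pathway model
#'
#' Estimates the hierarchical structured-component model
#' `g(mu_iq) = beta_0q + sum_k f_ik beta_kq`, `f_ik = sum_t x_ikt w_tk`,
#' by alternating closed-form ridge-GLS solves: update B for fixed W
#' ([update_B()]), update W for fixed B ([update_W()]), then update the
#' working correlation and dispersion from Pearson residuals, repeating
#' until the largest absolute parameter change falls below `tol`.
#'
#' Separate ridge penalties apply to the gene-to-pathway weights
#' (`lambda_G`) and pathway-to-phenotype coefficients (`lambda_P`);
#' intercepts are not penalized. After convergence each pathway's weight
#' block and coefficient row are jointly sign-flipped so the
#' largest-magnitude weight is positive (removing the sign indeterminacy
#' of the component).
#'
#' @param design a `pharaoh_design` from [build_design()].
#' @param Y N x Q numeric phenotype matrix (complete cases; values in
#'   \{0,1\} for the binomial family).
#' @param family `"gaussian"` (identity link) or `"binomial"` (logit link).
#' @param lambda_G,lambda_P non-negative ridge penalties.
#' @param corstr working correlation structure: `"independence"`,
#'   `"exchangeable"`, `"ar1"` or `"unstructured"`.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   free parameters (default 1e-5).
#' @param max_iter maximum number of alternating iterations (default 200).
#' @param estimate_phi if `TRUE` the dispersion is estimated from Pearson
#'   residuals; default `TRUE` for gaussian, `FALSE` (phi = 1) for
#'   binomial.
#' @param standardize_components if `TRUE`, component scores are rescaled
#'   to unit variance each iteration (off by default; the ridge penalties
#'   control the component scale).
#' @param sign_convention apply the per-pathway sign normalization
#'   (default `TRUE`).
#' @param verbose if `TRUE`, log the penalized objective per iteration.
#' @return an object of class `pharaoh_gee` with elements `W` (full weight
#'   matrix), `w` (free weights), `B`, `F` (component scores), `alpha`
#'   (working correlation), `phi`, `residuals` (Pearson), `fitted`,
#'   `linear_predictors`, `n_iter`, `converged`, `objective_trace`, and the
#'   call settings.
#' @export
pharaoh_gee <- function(design, Y, family = c("gaussian", "binomial"),
                        lambda_G = 1, lambda_P = 1,
                        corstr = c("independence", "exchangeable", "ar1",
                                   "unstructured"),
                        tol = 1e-5, max_iter = 200, estimate_phi = NULL,
                        standardize_components = FALSE,
                        sign_convention = TRUE, verbose = FALSE) {
  stopifnot(inherits(design, "pharaoh_design"))
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  stopifnot(lambda_G >= 0, lambda_P >= 0)
  Y <- as_phenotype_matrix(Y)
  if (nrow(Y) != design$N) stop("phenotype rows must match design samples")
  if (family == "binomial") check_binary(Y)
  if (is.null(estimate_phi)) estimate_phi <- family == "gaussian"
  N <- design$N; Q <- ncol(Y); K <- design$K
  map <- as.integer(design$block$k)

  # deterministic, scale-consistent initialization
  w <- 1 / sqrt(design$Tk[map])
  B <- matrix(0, K + 1, Q)
  ybar <- colMeans(Y)
  if (family == "binomial") ybar <- pmin(pmax(ybar, 0.01), 0.99)
  B[1, ] <- link_fun(ybar, family)
  rownames(B) <- c("(Intercept)", design$pathways)
  colnames(B) <- colnames(Y) %||% paste0("Y", seq_len(Q))

  R <- diag(Q); alpha <- list(structure = corstr, alpha = numeric(0), R = R)
  phi <- 1
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  if (!standardize_components && getOption("pharaohgee.engine", TRUE)) {
    # compiled fast path: identical algorithm to the reference loop below
    eng <- fit_engine_cpp(design$X, Y, as.integer(map) - 1L, w, B,
                          match(family, c("gaussian", "binomial")) - 1L,
                          match(corstr, c("independence", "exchangeable",
                                          "ar1", "unstructured")) - 1L,
                          lambda_G, lambda_P, tol, max_iter, estimate_phi,
                          getOption("pharaohgee.aa_depth", 3L),
                          getOption("pharaohgee.aa_cap", 25))
    B <- eng$B; dimnames(B) <- list(c("(Intercept)", design$pathways),
                                    colnames(Y) %||%
                                      paste0("Y", seq_len(Q)))
    w <- drop(eng$w)
    phi <- eng$phi
    iter <- eng$n_iter
    converged <- eng$converged
    trace <- as.numeric(eng$trace)
    alpha <- alpha_from_R(eng$R, corstr)
    if (verbose && length(trace))
      message(paste0("iter ", seq_along(trace), ": objective ",
                     signif(trace, 6), collapse = "\n"))
    if (!converged)
      warning("pharaoh_gee did not converge in ", iter,
              " iterations (last change ", signif(eng$last_delta, 3),
              "); returning the best iterate")
    return(finish_fit(design, Y, B, w, map, K, alpha, phi, iter,
                      converged, trace, family, corstr, lambda_G,
                      lambda_P, tol, sign_convention))
  }

  obj_best <- NA_real_; B_best <- B; w_best <- w
  Rinv <- diag(Q)
  Fm <- comp_scores_free(design$X, w, map, K)
  # Anderson acceleration history of the fixed-point map (one alternation
  # sweep): residuals f = G(theta) - theta and map values g = G(theta)
  aa_depth <- getOption("pharaohgee.aa_depth", 3L)
  aa_cap <- getOption("pharaohgee.aa_cap", 25)
  f_hist <- list(); g_hist <- list()
  nB <- length(B)
  while (iter < max_iter) {
    iter <- iter + 1L
    B_new <- update_B_core(Fm, B, Y, family, Rinv, phi, lambda_P)
    w_new <- update_W_core(design, Fm, B_new, Y, family, Rinv, phi,
                           lambda_G)
    if (lambda_G > 0 && lambda_P > 0) {
      # jump along the scale-indeterminate direction (w_k * c, beta_k / c)
      # to the ridge-balanced scale lambda_G||w_k||^2 = lambda_P||b_k||^2;
      # eta-invariant, and a no-op at any fixed point of the alternation
      for (k in seq_len(K)) {
        idx <- which(map == k)
        nw <- sqrt(sum(w_new[idx]^2)); nb <- sqrt(sum(B_new[k + 1, ]^2))
        if (nw > 1e-12 && nb > 1e-12) {
          cc <- (lambda_P / lambda_G)^0.25 * sqrt(nb / nw)
          w_new[idx] <- w_new[idx] * cc
          B_new[k + 1, ] <- B_new[k + 1, ] / cc
        }
      }
    }
    if (standardize_components) {
      Fm <- comp_scores_free(design$X, w_new, map, K)
      s <- sqrt(colSums(scale(Fm[, -1, drop = FALSE], scale = FALSE)^2) / N)
      s[s == 0] <- 1
      w_new <- w_new / s[map]
      B_new[-1, ] <- B_new[-1, , drop = FALSE] * s
    }
    g_vec <- c(B_new, w_new)
    f_vec <- g_vec - c(B, w)
    delta <- max(abs(f_vec))
    if (!is.finite(delta) || delta > 1e6) {
      # diverged (can happen for binomial fits with extreme predictors);
      # fall back to the best iterate seen
      B <- B_best; w <- w_best
      break
    }
    if (delta < tol) { B <- B_new; w <- w_new; converged <- TRUE; break }
    # Anderson mixing: combine the last few map evaluations to cancel the
    # slowly contracting modes of the alternation. The fixed point is
    # unchanged; convergence is still judged by the raw sweep residual.
    f_hist <- c(f_hist, list(f_vec)); g_hist <- c(g_hist, list(g_vec))
    if (length(f_hist) > aa_depth + 1L) {
      f_hist <- f_hist[-1]; g_hist <- g_hist[-1]
    }
    m <- length(f_hist) - 1L
    theta_next <- g_vec
    if (m >= 1L && aa_depth > 0L && delta > 10 * tol) {
      dF <- vapply(seq_len(m), function(j)
        f_hist[[m + 1 - j + 1]] - f_hist[[m + 1 - j]], numeric(length(f_vec)))
      gam <- tryCatch(qr.solve(dF, f_vec), error = function(e) NULL)
      if (!is.null(gam) && all(is.finite(gam)) && max(abs(gam)) <= aa_cap) {
        dG <- vapply(seq_len(m), function(j)
          g_hist[[m + 1 - j + 1]] - g_hist[[m + 1 - j]],
          numeric(length(f_vec)))
        theta_next <- g_vec - drop(dG %*% gam)
      }
    }
    B <- matrix(theta_next[seq_len(nB)], K + 1, Q, dimnames = dimnames(B))
    w <- theta_next[nB + seq_along(w)]
    Fm <- comp_scores_free(design$X, w, map, K)
    eta <- Fm %*% B
    mu <- linkinv_fun(eta, family)
    res <- pearson_residuals(Y, mu, family)
    phi <- if (estimate_phi) estimate_dispersion(res, K, design$Tk) else 1
    alpha <- estimate_alpha(res, phi, corstr)
    Rinv <- solve(alpha$R)
    trace <- c(trace, quasi_deviance(Y, mu, family) +
                 lambda_P * sum(B[-1, ]^2) + lambda_G * sum(w^2))
    obj <- trace[length(trace)]
    if (verbose)
      message("iter ", iter, ": max change ", signif(delta, 4),
              ", objective ", signif(obj, 6))
    if (is.finite(obj) && (is.na(obj_best) || obj < obj_best)) {
      obj_best <- obj; B_best <- B; w_best <- w
    }
  }
  if (!converged) {
    if (!is.na(obj_best)) { B <- B_best; w <- w_best }
    warning("pharaoh_gee did not converge in ", iter,
            " iterations (last change ", signif(delta, 3),
            "); returning the best iterate")
  }
  finish_fit(design, Y, B, w, map, K, alpha, phi, iter, converged, trace,
             family, corstr, lambda_G, lambda_P, tol, sign_convention)
}

# working-correlation summary from an estimated R matrix
alpha_from_R <- function(R, corstr) {
  alpha <- switch(corstr,
                  independence = numeric(0),
                  exchangeable = if (ncol(R) > 1) R[1, 2] else numeric(0),
                  ar1 = if (ncol(R) > 1) R[1, 2] else numeric(0),
                  unstructured = R[upper.tri(R)])
  list(structure = corstr, alpha = alpha, R = R)
}

# sign normalization, fitted quantities and the classed result object
finish_fit <- function(design, Y, B, w, map, K, alpha, phi, iter,
                       converged, trace, family, corstr, lambda_G,
                       lambda_P, tol, sign_convention) {
  if (sign_convention) {
    for (k in seq_len(K)) {
      idx <- which(map == k)
      if (w[idx][which.max(abs(w[idx]))] < 0) {
        w[idx] <- -w[idx]
        B[k + 1, ] <- -B[k + 1, ]
      }
    }
  }
  Fm <- comp_scores_free(design$X, w, map, K)
  eta <- Fm %*% B
  mu <- linkinv_fun(eta, family)
  res <- pearson_residuals(Y, mu, family)
  W <- expand_weights(w, map, K)
  dimnames(W) <- list(colnames(design$X),
                      c("(Intercept)", design$pathways))
  names(w) <- colnames(design$X)[-1]

  structure(list(W = W, w = w, B = B, F = Fm, alpha = alpha, phi = phi,
                 residuals = res, fitted = mu, linear_predictors = eta,
                 n_iter = iter, converged = converged,
                 objective_trace = trace, family = family, corstr = corstr,
                 lambda_G = lambda_G, lambda_P = lambda_P,
                 design = design, Y = Y, tol = tol),
            class = "pharaoh_gee")
}

#' @exportS3Method base::print
print.pharaoh_gee <- function(x, ...) {
  cat("Penalized GEE pathway model (", x$family, "/", x$corstr, ")\n", sep = "")
  cat("  N =", x$design$N, " pathways =", x$design$K,
      " genes =", length(x$w), " phenotypes =", ncol(x$Y), "\n")
  cat("  lambda_G =", x$lambda_G, " lambda_P =", x$lambda_P,
      " phi =", signif(x$phi, 4), "\n")
  cat("  ", if (x$converged) "converged" else "NOT converged", "in",
      x$n_iter, "iterations\n")
  cat("Pathway coefficients (B):\n")
  print(signif(x$B, 4))
  invisible(x)
}

#' @export
coef.pharaoh_gee <- function(object, ...) object$B

#' @export
fitted.pharaoh_gee <- function(object, ...) object$fitted

#' @export
residuals.pharaoh_gee <- function(object, type = c("pearson", "response"),
                                  ...) {
  type <- match.arg(type)
  if (type == "pearson") object$residuals
  else object$Y - object$fitted
}

#' Predict from a fitted pathway model
#'
#' @param object a `pharaoh_gee` fit.
#' @param newdata optional `pharaoh_design` or standardized design matrix
#'   with the same columns as the training design; defaults to the
#'   training design.
#' @param type `"link"` for linear predictors, `"response"` for means.
#' @param ... unused.
#' @return N x Q matrix of predictions.
#' @export
predict.pharaoh_gee <- function(object, newdata = NULL,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$design$X
       else if (inherits(newdata, "pharaoh_design")) newdata$X
       else as.matrix(newdata)
  eta <- component_scores(X, object$W) %*% object$B
  if (type == "link") eta else linkinv_fun(eta, object$family)
}

#' @export
summary.pharaoh_gee <- function(object, ...) {
  w_by_pw <- split(object$w, object$design$block$pathway)
  out <- list(fit = object,
              B = object$B,
              weight_norms = vapply(w_by_pw, function(v) sqrt(sum(v^2)),
                                    numeric(1)),
              alpha = object$alpha, phi = object$phi,
              quasi_deviance = quasi_deviance(object$Y, object$fitted,
                                              object$family))
  class(out) <- "summary.pharaoh_gee"
  out
}

#' @exportS3Method base::print
print.summary.pharaoh_gee <- function(x, ...) {
  print(x$fit)
  cat("Per-pathway weight norms:\n")
  print(signif(x$weight_norms, 4))
  if (length(x$alpha$alpha))
    cat("Working correlation alpha:", signif(x$alpha$alpha, 4), "\n")
  cat("Quasi-deviance:", signif(x$quasi_deviance, 6), "\n")
  invisible(x)
}

#' @exportS3Method base::plot
plot.pharaoh_gee <- function(x, ...) {
  plot(seq_along(x$objective_trace), x$objective_trace, type = "b",
       xlab = "iteration", ylab = "penalized quasi-deviance",
       main = "Fit objective trace", ...)
  invisible(x)
}
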