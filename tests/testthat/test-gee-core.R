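test_that("component scores are X W with an intercept pseudo-component", {
  d <- tiny_design(N = 12, Tk = c(2, 3), seed = 2)
  w <- c(0.5, -1, 2, 0.3, 1)
  W <- matrix(0, 6, 3); W[1, 1] <- 1
  W[cbind(2:6, d$block$k + 1)] <- w
  Fm <- component_scores(d$X, W)
  expect_equal(Fm[, 1], rep(1, 12))
  # elementwise double-sum oracle
  for (k in 1:2) {
    idx <- which(d$block$k == k)
    manual <- sapply(seq_len(12), function(i)
      sum(d$X[i, idx + 1] * w[idx]))
    expect_equal(Fm[, k + 1], manual)
  }
  # single gene, unit weight: component equals the column
  d1 <- tiny_design(N = 8, Tk = 1, seed = 3)
  W1 <- diag(2)
  expect_equal(component_scores(d1$X, W1)[, 2], d1$X[, 2])
  expect_error(component_scores(d$X, diag(3)), "non-conforming")
})

test_that("working covariance is phi A^1/2 R A^1/2", {
  expect_equal(working_covariance(c(0, 0), diag(2), "gaussian", 1), diag(2))
  expect_equal(working_covariance(c(0.5, 0.5), diag(2), "binomial", 1),
               diag(0.25, 2))
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  S <- working_covariance(c(0.5, 0.5), R, "binomial", 1)
  expect_equal(S[1, 2], 0.125)
  expect_equal(S[1, 1], 0.25)
  # dispersion scales the whole matrix
  expect_equal(working_covariance(c(0.2, 0.8), R, "binomial", 2),
               2 * working_covariance(c(0.2, 0.8), R, "binomial", 1))
  expect_warning(working_covariance(c(0, 0.5), diag(2), "binomial"),
                 "clamped")
})

test_that("Pearson residuals match the hand formula", {
  expect_equal(pearson_residuals(matrix(3), matrix(1), "gaussian"),
               matrix(2))
  expect_equal(pearson_residuals(matrix(1), matrix(0.5), "binomial"),
               matrix(1))
  expect_equal(pearson_residuals(matrix(0), matrix(0.8), "binomial"),
               matrix(-0.8 / sqrt(0.16)))
})

test_that("dispersion is the residual sum of squares over the model df", {
  r <- matrix(2, 10, 2)
  expect_equal(estimate_dispersion(r, K = 1, Tk = 5), 20 * 4 / 14)
  expect_equal(estimate_dispersion(matrix(0, 5, 3), 1, 2), 0)
  set.seed(1)
  r2 <- matrix(rnorm(24), 8, 3)
  manual <- 0
  for (i in 1:8) for (j in 1:3) manual <- manual + r2[i, j]^2
  expect_equal(estimate_dispersion(r2, K = 2, Tk = c(3, 4)),
               manual / (24 - 9))
  expect_error(estimate_dispersion(matrix(0, 2, 2), 2, c(2, 2)),
               "degrees of freedom")
})

test_that("working correlation moment estimators behave per structure", {
  set.seed(5)
  r <- matrix(rnorm(60), 20, 3)
  expect_equal(estimate_alpha(r, 1, "independence")$R, diag(3))
  # perfect correlation caps below 1
  r2 <- cbind(r[, 1], r[, 1], r[, 2])
  a2 <- estimate_alpha(r2, phi = mean(r[, 1]^2), "unstructured")
  expect_lte(a2$R[1, 2], 0.99)
  expect_gt(a2$R[1, 2], 0.9)
  expect_equal(diag(a2$R), rep(1, 3))
  # exchangeable alpha recovers the generating correlation at large N
  set.seed(6)
  Z <- MASS::mvrnorm(2000, rep(0, 4),
                     0.4 + diag(0.6, 4))
  a3 <- estimate_alpha(Z, phi = 1, "exchangeable")
  expect_lt(abs(a3$alpha - 0.4), 0.05)
  # ar1 estimator uses lag-1 products
  set.seed(7)
  a4 <- estimate_alpha(r, phi = 1, "ar1")
  manual <- mean(r[, 1:2] * r[, 2:3])
  expect_equal(a4$alpha, manual)
  expect_equal(a4$R[1, 3], manual^2)
})

test_that("update_B matches the dense stacked-system oracle", {
  for (case in list(list(Tk = c(2, 1), Q = 2, family = "gaussian",
                         lam = 0.7, seed = 10),
                    list(Tk = c(2, 2), Q = 3, family = "binomial",
                         lam = 1.3, seed = 11),
                    list(Tk = 1, Q = 1, family = "gaussian",
                         lam = 0, seed = 12))) {
    d <- tiny_design(N = 9, Tk = case$Tk, seed = case$seed)
    K <- d$K; Q <- case$Q
    set.seed(case$seed + 100)
    Y <- if (case$family == "binomial")
      matrix(rbinom(9 * Q, 1, 0.5), 9) else matrix(rnorm(9 * Q), 9)
    w <- runif(nrow(d$block), -1, 1)
    B <- matrix(rnorm((K + 1) * Q, sd = 0.3), K + 1)
    R <- 0.3 + diag(0.7, Q)
    got <- update_B(d, w, B, Y, case$family, R, phi = 1.2,
                    lambda_P = case$lam)
    want <- oracle_update_B(d, w, B, Y, case$family, R, 1.2, case$lam)
    expect_equal(unname(got), want, tolerance = 1e-8)
  }
})

test_that("update_W matches the dense stacked-system oracle", {
  for (case in list(list(Tk = c(2, 2), Q = 2, family = "gaussian",
                         lam = 0.5, seed = 20),
                    list(Tk = c(3, 1), Q = 3, family = "binomial",
                         lam = 2, seed = 21))) {
    d <- tiny_design(N = 10, Tk = case$Tk, seed = case$seed)
    K <- d$K; Q <- case$Q
    set.seed(case$seed + 100)
    Y <- if (case$family == "binomial")
      matrix(rbinom(10 * Q, 1, 0.5), 10) else matrix(rnorm(10 * Q), 10)
    w <- runif(nrow(d$block), -1, 1)
    B <- matrix(rnorm((K + 1) * Q, sd = 0.4), K + 1)
    R <- 0.25 + diag(0.75, Q)
    got <- update_W(d, w, B, Y, case$family, R, phi = 0.8,
                    lambda_G = case$lam)
    want <- oracle_update_W(d, w, B, Y, case$family, R, 0.8, case$lam)
    expect_equal(unname(got), drop(want), tolerance = 1e-8)
  }
})

test_that("huge ridge penalties shrink the free parameters to zero", {
  d <- tiny_design(N = 30, Tk = c(2, 2), seed = 30)
  set.seed(31)
  Y <- matrix(rnorm(60), 30)
  w <- rep(0.5, 4)
  B <- matrix(0.5, 3, 2)
  Bp <- update_B(d, w, B, Y, "gaussian", diag(2), 1, lambda_P = 1e12)
  expect_lt(max(abs(Bp[-1, ])), 1e-6)
  expect_equal(Bp[1, ], colMeans(Y), tolerance = 1e-6)  # intercept unpenalized
  wp <- update_W(d, w, B, Y, "gaussian", diag(2), 1, lambda_G = 1e12)
  expect_lt(max(abs(wp)), 1e-6)
})

test_that("single-pathway single-gene weight update is the offset regression slope", {
  d <- tiny_design(N = 25, Tk = 1, seed = 33)
  set.seed(34)
  y <- matrix(2 + 1.5 * d$X[, 2] + rnorm(25, sd = 0.2))
  B <- matrix(c(2, 1), 2, 1)  # beta0 = 2, beta1 = 1 fixed
  w <- update_W(d, 1, B, y, "gaussian", matrix(1), 1, lambda_G = 0)
  slope <- sum(d$X[, 2] * (y - 2)) / sum(d$X[, 2]^2)
  expect_equal(w, slope, tolerance = 1e-10)
})

test_that("structural zeros and block separation are preserved", {
  d <- tiny_design(N = 40, Tk = c(3, 3), seed = 40)
  set.seed(41)
  Y <- matrix(rnorm(80), 40)
  fit <- pharaoh_gee(d, Y, family = "gaussian", lambda_G = 0.5,
                     lambda_P = 0.5, corstr = "independence")
  W <- fit$W
  expect_equal(unname(W[1, 1]), 1)
  expect_true(all(W[2:4, 3] == 0))
  expect_true(all(W[5:7, 2] == 0))
  expect_true(all(W[1, 2:3] == 0))
  expect_equal(unname(fit$F), unname(component_scores(d$X, W)))
})

test_that("gaussian K=T=1 unpenalized fit reproduces the OLS slope via w*beta", {
  d <- tiny_design(N = 50, Tk = 1, seed = 50)
  set.seed(51)
  y <- 0.8 * d$X[, 2] + rnorm(50, sd = 0.4)
  fit <- pharaoh_gee(d, y, family = "gaussian", lambda_G = 0,
                     lambda_P = 0, corstr = "independence")
  ols <- stats::lm(y ~ d$X[, 2])
  expect_equal(unname(fit$w * fit$B[2, 1]), unname(coef(ols)[2]),
               tolerance = 1e-6)
  expect_equal(unname(fit$B[1, 1]), unname(coef(ols)[1]), tolerance = 1e-6)
  # fitted values match unrestricted least squares
  expect_equal(unname(drop(fit$fitted)), unname(fitted(ols)),
               tolerance = 1e-6)
})

test_that("ridge norms are monotone non-increasing in their penalties", {
  d <- tiny_design(N = 60, Tk = c(3, 3), seed = 60)
  set.seed(61)
  Y <- matrix(rnorm(120), 60) + drop(d$X[, 2:3] %*% c(0.5, 0.3))
  grid <- c(0.01, 0.1, 1, 10, 100)
  bnorm <- sapply(grid, function(lp)
    sqrt(sum(pharaoh_gee(d, Y, family = "gaussian", lambda_G = 1,
                         lambda_P = lp,
                         corstr = "independence")$B[-1, ]^2)))
  expect_true(all(diff(bnorm) <= 1e-8))
  wnorm <- sapply(grid, function(lg)
    sqrt(sum(pharaoh_gee(d, Y, family = "gaussian", lambda_G = lg,
                         lambda_P = 1,
                         corstr = "independence")$w^2)))
  expect_true(all(diff(wnorm) <= 1e-8))
})

test_that("the linear predictor is invariant to pathway rescaling (w c, beta/c)", {
  d <- tiny_design(N = 20, Tk = c(2, 2), seed = 70)
  set.seed(71)
  Y <- matrix(rnorm(40), 20)
  fit <- pharaoh_gee(d, Y, family = "gaussian", lambda_G = 1, lambda_P = 1,
                     corstr = "independence")
  w2 <- fit$w; B2 <- fit$B
  idx <- which(d$block$k == 1)
  w2[idx] <- w2[idx] * 3
  B2[2, ] <- B2[2, ] / 3
  W2 <- fit$W; W2[idx + 1, 2] <- W2[idx + 1, 2] * 3
  eta2 <- component_scores(d$X, W2) %*% B2
  expect_equal(eta2, fit$linear_predictors, tolerance = 1e-12)
})

test_that("compiled engine and reference R loop agree to machine precision", {
  tg <- tiny_genotypes(seed = 80, N = 60, K = 3, genes_per_pathway = 3)
  d <- build_design(tg$genotypes, tg$annotation)
  set.seed(81)
  Yb <- matrix(rbinom(180, 1, 0.5), 60)
  Yg <- matrix(rnorm(180), 60)
  for (case in list(list(Y = Yb, fam = "binomial", cs = "exchangeable"),
                    list(Y = Yg, fam = "gaussian", cs = "unstructured"),
                    list(Y = Yg, fam = "gaussian", cs = "ar1"))) {
    f_cpp <- pharaoh_gee(d, case$Y, family = case$fam, lambda_G = 1,
                         lambda_P = 1, corstr = case$cs)
    old <- options(pharaohgee.engine = FALSE); on.exit(options(old))
    f_r <- pharaoh_gee(d, case$Y, family = case$fam, lambda_G = 1,
                       lambda_P = 1, corstr = case$cs)
    options(old)
    expect_equal(f_cpp$B, f_r$B, tolerance = 1e-12)
    expect_equal(f_cpp$w, f_r$w, tolerance = 1e-12)
    expect_equal(f_cpp$alpha$R, f_r$alpha$R, tolerance = 1e-12)
    expect_equal(f_cpp$phi, f_r$phi, tolerance = 1e-12)
  }
})

test_that("product w*beta is recovered under a misspecified working correlation", {
  # exchangeable-correlated gaussian data fitted with independence R:
  # GEE point estimates stay consistent
  set.seed(90)
  N <- 1500
  x <- rnorm(N)
  d <- standardize_design(cbind(1, x))
  eta <- 0.5 * d$X[, 2]
  E <- MASS::mvrnorm(N, c(0, 0), matrix(c(1, 0.6, 0.6, 1), 2))
  Y <- cbind(eta + E[, 1], eta + E[, 2])
  fit <- pharaoh_gee(d, Y, family = "gaussian", lambda_G = 1e-4,
                     lambda_P = 1e-4, corstr = "independence")
  prod <- fit$w * fit$B[2, ]
  expect_lt(max(abs(prod - 0.5)), 3 / sqrt(N))
})

test_that("fit on null data keeps pathway effects small and converges", {
  d <- tiny_design(N = 80, Tk = c(3, 3), seed = 95)
  set.seed(96)
  Y <- matrix(rnorm(160), 80)
  fit <- pharaoh_gee(d, Y, family = "gaussian", lambda_G = 1, lambda_P = 1,
                     corstr = "independence")
  expect_true(fit$converged)
  # eta carries far less variance than the noise under the null
  expect_lt(stats::var(as.vector(fit$linear_predictors - matrix(
    fit$B[1, ], 80, 2, byrow = TRUE))), 0.5)
})
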