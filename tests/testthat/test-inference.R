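test_that("Wald statistic is the covariance-weighted quadratic form", {
  expect_equal(wald_statistic(c(1, 1), diag(2)), 2)
  expect_equal(wald_statistic(2, matrix(4)), 1)
  set.seed(1)
  beta <- rnorm(3)
  A <- matrix(rnorm(9), 3)
  V <- crossprod(A) + diag(0.1, 3)
  expect_equal(wald_statistic(beta, V),
               drop(t(beta) %*% solve(V) %*% beta))
  # invariance under a common invertible reparameterization
  C <- matrix(c(2, 1, 0, 0, 1, 3, 1, 0, 1), 3)
  expect_equal(wald_statistic(drop(C %*% beta), C %*% V %*% t(C)),
               wald_statistic(beta, V), tolerance = 1e-10)
  expect_warning(wald_statistic(c(1, 1), matrix(0, 2, 2)), "pseudo-inverse")
})

test_that("permutation covariance is the sample covariance of null betas", {
  expect_equal(permutation_covariance(matrix(1, 10, 2)),
               matrix(0, 2, 2))
  nb <- rbind(c(0, 0), c(2, 2), c(0, 0), c(2, 2))
  expect_equal(permutation_covariance(nb),
               matrix(4 / 3, 2, 2))
  set.seed(2)
  big <- MASS::mvrnorm(5000, c(0, 0), matrix(c(2, 0.8, 0.8, 1), 2))
  expect_equal(permutation_covariance(big),
               matrix(c(2, 0.8, 0.8, 1), 2), tolerance = 0.1)
  expect_error(permutation_covariance(matrix(0, 3, 2)), "at least")
})

test_that("BH q-values equal the hand step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  # independent hand implementation of the step-up on a scrambled vector
  p <- c(0.04, 0.001, 0.9, 0.02, 0.3)
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  want <- numeric(m); want[o] <- q_sorted
  expect_equal(bh_fdr(p), want)
  # ranking of p-values is preserved
  expect_equal(order(bh_fdr(p)[order(p)]), seq_len(m))
})

test_that("Westfall-Young max-T dominates the raw p and collapses for K=1", {
  set.seed(3)
  null_T <- matrix(rchisq(200 * 3, df = 2), 200)
  T_obs <- c(1, 5, 12)
  wy <- westfall_young(null_T, T_obs)
  raw <- sapply(1:3, function(k)
    (1 + sum(null_T[, k] >= T_obs[k])) / 201)
  expect_true(all(wy >= raw))
  expect_true(all(diff(wy[order(T_obs)]) <= 0))
  expect_equal(westfall_young(null_T[, 1, drop = FALSE], T_obs[1]), raw[1])
  expect_equal(westfall_young(null_T, c(1e9, 1e9, 1e9)),
               rep(1 / 201, 3))
})

test_that("sandwich covariance reduces to the classical GEE sandwich", {
  # lambda = 0, gaussian, independence, Q = 1: textbook sandwich for the
  # regression of y on [1, f]
  d <- tiny_design(N = 30, Tk = 1, seed = 700)
  set.seed(701)
  y <- matrix(1 + 0.6 * d$X[, 2] + rnorm(30, sd = 0.5))
  fit <- pharaoh_gee(d, y, family = "gaussian", lambda_G = 0, lambda_P = 0,
                     corstr = "independence")
  sw <- sandwich_covariance(fit)
  Fm <- fit$F
  e <- drop(y - fit$fitted)
  bread <- solve(crossprod(Fm) / fit$phi)
  meat <- t(Fm * e / fit$phi) %*% (Fm * e / fit$phi)
  want <- bread %*% meat %*% bread
  expect_equal(unname(sw$cov), unname(want), tolerance = 1e-6)
  # zero residuals give a zero covariance
  y0 <- matrix(fit$fitted)
  fit0 <- fit; fit0$Y <- y0; fit0$fitted <- fit$fitted
  fit0$residuals <- matrix(0, 30, 1)
  sw0 <- sandwich_covariance(fit0)
  expect_equal(max(abs(sw0$M)), 0)
  expect_equal(max(abs(sw0$cov)), 0)
})

test_that("sandwich matches a hand-assembled scalar toy", {
  # N = 3, one component, gaussian, phi fixed by hand recomputation
  X_raw <- cbind(1, c(1, 0, -1))
  d <- standardize_design(X_raw)
  y <- matrix(c(2, 0, -1))
  fit <- pharaoh_gee(d, y, family = "gaussian", lambda_G = 0, lambda_P = 0,
                     corstr = "independence")
  sw <- sandwich_covariance(fit)
  f <- fit$F
  e <- drop(y - fit$fitted)
  H <- t(f) %*% f / fit$phi
  M <- t(f * e) %*% (f * e) / fit$phi^2
  expect_equal(unname(sw$cov), unname(solve(H) %*% M %*% solve(H)),
               tolerance = 1e-8)
})

test_that("permutation test p-values follow the add-one rule and are deterministic", {
  tg <- tiny_genotypes(seed = 800, N = 80, K = 2, genes_per_pathway = 2)
  d <- build_design(tg$genotypes, tg$annotation)
  set.seed(801)
  # strong association with pathway 1's genes
  eta <- drop(scale(d$X[, 2]))
  Y <- cbind(eta, eta) + matrix(rnorm(160, sd = 0.4), 80)
  pt1 <- pharaoh_perm_test(d, Y, lambda_G = 0.5, lambda_P = 0.5,
                           family = "gaussian", corstr = "exchangeable",
                           n_perm = 99, seed = 5, force = TRUE) |>
    suppressWarnings()
  # the causal pathway beats every permutation: p = 1/(n_perm + 1)
  expect_equal(pt1$pathways$p[1], 1 / 100)
  expect_true(all(pt1$pathways$p >= 1 / 100 & pt1$pathways$p <= 1))
  expect_true(all(pt1$pathways$wy_p >= pt1$pathways$p - 1e-12))
  # same seed, same run: byte-identical results
  pt2 <- pharaoh_perm_test(d, Y, lambda_G = 0.5, lambda_P = 0.5,
                           family = "gaussian", corstr = "exchangeable",
                           n_perm = 99, seed = 5, force = TRUE) |>
    suppressWarnings()
  expect_identical(pt1$pathways, pt2$pathways)
  expect_identical(pt1$genes, pt2$genes)
  # gene-level results cover every design column
  expect_equal(nrow(pt1$genes), nrow(d$block))
  expect_true(all(pt1$genes$p >= 1 / 100 & pt1$genes$p <= 1))
  # causal genes rank ahead of the null pathway's genes
  expect_lt(mean(pt1$genes$p[pt1$genes$pathway == "P1"]),
            mean(pt1$genes$p[pt1$genes$pathway == "P2"]))
})

test_that("a statistic at the null median gets p near one half", {
  set.seed(9)
  null_T <- matrix(rchisq(400, 2), ncol = 1)
  p <- (1 + sum(null_T[, 1] >= stats::median(null_T[, 1]))) / 401
  expect_lt(abs(p - 0.5), 0.05)
})
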