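# Small fixtures built in code; all randomness behind explicit seeds.

# random standardized design with K pathways of Tk genes each
tiny_design <- function(N = 20, Tk = c(2, 2), seed = 1) {
  set.seed(seed)
  K <- length(Tk)
  X_raw <- cbind(1, matrix(rnorm(N * sum(Tk)), N))
  block <- data.frame(k = rep(seq_len(K), Tk),
                      pathway = rep(paste0("P", seq_len(K)), Tk),
                      gene = paste0("G", seq_len(sum(Tk))),
                      stringsAsFactors = FALSE)
  standardize_design(X_raw, block = block,
                     pathways = paste0("P", seq_len(K)))
}

# dense, loop-based oracle for the coefficient update system:
# (sum_i Q_i' Om_i Q_i + lambda_P D) b = sum_i Q_i' Om_i z_i with
# Q_i = f_i' (x) I_Q, Om_i the IRLS cluster weight, z the working response
oracle_update_B <- function(design, w, B, Y, family, R, phi, lambda_P) {
  Y <- as.matrix(Y)
  Q <- ncol(Y); K <- design$K
  W <- matrix(0, nrow(design$block) + 1, K + 1)
  W[1, 1] <- 1
  W[cbind(seq_len(nrow(design$block)) + 1, design$block$k + 1)] <- w
  Fm <- design$X %*% W
  eta <- Fm %*% B
  if (family == "gaussian") {
    z <- Y
    om_half <- matrix(1, nrow(Y), Q)
  } else {
    mu <- plogis(eta)
    nu <- mu * (1 - mu)
    z <- eta + (Y - mu) / nu
    om_half <- sqrt(nu)
  }
  P <- K + 1
  LHS <- matrix(0, P * Q, P * Q)
  RHS <- numeric(P * Q)
  for (i in seq_len(nrow(Y))) {
    Qi <- kronecker(t(Fm[i, ]), diag(Q))   # Q x PQ, column order (a, q)
    Om <- diag(om_half[i, ], Q) %*% solve(R) %*% diag(om_half[i, ], Q) / phi
    LHS <- LHS + t(Qi) %*% Om %*% Qi
    RHS <- RHS + t(Qi) %*% Om %*% z[i, ]
  }
  D <- rep(1, P * Q); D[seq_len(Q)] <- 0
  b <- solve(LHS + lambda_P * diag(D), RHS)
  matrix(b, nrow = P, ncol = Q, byrow = TRUE)
}

# dense, loop-based oracle for the weight update system
oracle_update_W <- function(design, w, B, Y, family, R, phi, lambda_G) {
  Y <- as.matrix(Y)
  Q <- ncol(Y); K <- design$K
  Tn <- nrow(design$block)
  W <- matrix(0, Tn + 1, K + 1); W[1, 1] <- 1
  W[cbind(seq_len(Tn) + 1, design$block$k + 1)] <- w
  Fm <- design$X %*% W
  eta <- Fm %*% B
  if (family == "gaussian") {
    z <- Y
    om_half <- matrix(1, nrow(Y), Q)
  } else {
    mu <- plogis(eta)
    nu <- mu * (1 - mu)
    z <- eta + (Y - mu) / nu
    om_half <- sqrt(nu)
  }
  LHS <- matrix(0, Tn, Tn); RHS <- numeric(Tn)
  for (i in seq_len(nrow(Y))) {
    # M_i columns: x_it * beta_{k(t), .}
    Mi <- sapply(seq_len(Tn), function(t)
      design$X[i, t + 1] * B[design$block$k[t] + 1, ])
    Mi <- matrix(Mi, nrow = Q)
    Om <- diag(om_half[i, ], Q) %*% solve(R) %*% diag(om_half[i, ], Q) / phi
    zr <- z[i, ] - B[1, ]
    LHS <- LHS + t(Mi) %*% Om %*% Mi
    RHS <- RHS + t(Mi) %*% Om %*% zr
  }
  solve(LHS + lambda_G * diag(Tn), RHS)
}

# tiny genotype set with a fully known annotation
tiny_genotypes <- function(seed = 1, N = 40, K = 2, genes_per_pathway = 2,
                           m = 3, maf = NULL) {
  set.seed(seed)
  G <- K * genes_per_pathway
  V <- G * m
  if (is.null(maf)) maf <- runif(V, 0.005, 0.04)
  dos <- matrix(rbinom(N * V, 2, rep(maf, each = N)), N)
  # guarantee polymorphism so no gene column is dropped
  for (j in seq_len(V)) if (all(dos[, j] == dos[1, j])) dos[j %% N + 1, j] <- 1
  geno <- genotype_matrix(dos, variant_ids = paste0("v", seq_len(V)),
                          maf = maf)
  v2g <- rep(paste0("G", seq_len(G)), each = m)
  names(v2g) <- paste0("v", seq_len(V))
  gmt <- split(paste0("G", seq_len(G)),
               rep(paste0("P", seq_len(K)), each = genes_per_pathway))
  annot <- pathway_annotation(v2g, gmt[order(names(gmt))])
  list(genotypes = geno, annotation = annot, maf = maf, v2g = v2g)
}
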