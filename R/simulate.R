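#' Simulation configuration
#'
#' Study conditions for the rare-variant pathway simulator: K pathways of
#' `genes_per_pathway` genes each, gene lengths drawn as a number of rare
#' variants per gene, rare MAFs drawn log-uniformly from `maf_range`,
#' genotypes binomial under Hardy-Weinberg equilibrium. Only pathway 1 is
#' causal: its first `H1` genes carry gene-level effect `w`, combined with
#' per-variant weights `|log10 MAF|` and pathway-level effect `beta` into
#' the latent linear predictor; Q binary phenotypes arise by thresholding
#' correlated (exchangeable `rho`) standard normals.
#'
#' @param N individuals (default 1000).
#' @param K pathways (default 10; the first is causal).
#' @param genes_per_pathway genes per pathway (default 10).
#' @param variants_per_gene integer range `c(min, max)` of rare variants
#'   per gene (default 5-20).
#' @param maf_range support of the log-uniform MAF spectrum
#'   (default `c(1e-4, 0.01)`).
#' @param H1 number of causal genes in pathway 1 (default 1).
#' @param w gene-level effect (default 0.5).
#' @param beta pathway-level effect (default 0.2).
#' @param rho exchangeable correlation of the latent phenotypes
#'   (default 0.25).
#' @param Q number of clustered phenotypes (default 3).
#' @return a `sim_config` list.
#' @export
sim_config <- function(N = 1000, K = 10, genes_per_pathway = 10,
                       variants_per_gene = c(5, 20),
                       maf_range = c(1e-4, 0.01),
                       H1 = 1, w = 0.5, beta = 0.2, rho = 0.25, Q = 3) {
  stopifnot(N >= 2, K >= 1, genes_per_pathway >= 1,
            H1 >= 0, H1 <= genes_per_pathway,
            rho >= 0, rho < 1, Q >= 1,
            length(variants_per_gene) %in% c(1, 2),
            all(maf_range > 0), all(maf_range <= 0.5))
  if (length(variants_per_gene) == 1)
    variants_per_gene <- rep(variants_per_gene, 2)
  structure(list(N = N, K = K, genes_per_pathway = genes_per_pathway,
                 variants_per_gene = as.integer(variants_per_gene),
                 maf_range = maf_range, H1 = H1, w = w, beta = beta,
                 rho = rho, Q = Q),
            class = "sim_config")
}

#' Simulate a pool of rare variants with genotypes
#'
#' Draws, per gene, a number of variants uniform on the configured range,
#' MAFs log-uniform on `maf_range`, and N x V genotypes as
#' `Binomial(2, MAF)` allele counts (Hardy-Weinberg). The stored MAF is
#' the generating (true) frequency, so collapsing weights match the
#' generative model.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `genotypes` (a [genotype_matrix()]), `annotation`
#'   (a [pathway_annotation()]), and `variants` (data frame: variant,
#'   gene, pathway, maf).
#' @export
simulate_variant_pool <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    G <- config$K * config$genes_per_pathway
    genes <- paste0("G", seq_len(G))
    pathway_of <- rep(paste0("P", seq_len(config$K)),
                      each = config$genes_per_pathway)
    m_range <- seq(config$variants_per_gene[1], config$variants_per_gene[2])
    m <- if (length(m_range) == 1) rep(m_range, G) else
      sample(m_range, G, replace = TRUE)
    gene_of_variant <- rep(genes, m)
    pw_of_variant <- rep(pathway_of, m)
    V <- sum(m)
    lo <- log(config$maf_range[1]); hi <- log(config$maf_range[2])
    maf <- if (lo == hi) rep(config$maf_range[1], V) else
      exp(runif(V, lo, hi))
    vids <- paste0("v", seq_len(V))
    dos <- matrix(rbinom(config$N * V, 2, rep(maf, each = config$N)),
                  nrow = config$N)
    geno <- genotype_matrix(dos,
                            sample_ids = paste0("S", seq_len(config$N)),
                            variant_ids = vids, maf = maf)
    v2g <- gene_of_variant; names(v2g) <- vids
    gmt <- split(genes, factor(pathway_of, levels = unique(pathway_of)))
    annot <- pathway_annotation(v2g, gmt)
    list(genotypes = geno, annotation = annot,
         variants = data.frame(variant = vids, gene = gene_of_variant,
                               pathway = pw_of_variant, maf = maf,
                               stringsAsFactors = FALSE))
  })
}

#' Latent linear predictor of the causal pathway
#'
#' `eta_iq = beta * sum_{t <= H1} w * sum_j |log10 MAF_tj| g_itj` over the
#' first `H1` genes of pathway 1; identical across the Q phenotypes
#' (a single pathway-level effect is shared by all phenotypes). With
#' `H1 = 0` the model is null and `eta` is identically zero.
#'
#' @param pool output of [simulate_variant_pool()].
#' @param config the [sim_config()] used to generate it.
#' @return N x Q matrix of linear predictors.
#' @export
simulate_linear_predictor <- function(pool, config) {
  stopifnot(inherits(config, "sim_config"))
  eta1 <- numeric(config$N)
  if (config$H1 > 0) {
    causal_genes <- paste0("G", seq_len(config$H1))
    for (g in causal_genes) {
      j <- which(pool$variants$gene == g)
      gamma <- abs(log10(pool$variants$maf[j]))
      burden <- pool$genotypes$dosages[, j, drop = FALSE] %*% gamma
      eta1 <- eta1 + config$w * drop(burden)
    }
    eta1 <- config$beta * eta1
  }
  matrix(eta1, config$N, config$Q)
}

#' Threshold correlated normals into clustered binary phenotypes
#'
#' Draws `Z_i ~ MVN(0, Sigma_rho)` with exchangeable correlation `rho` and
#' sets `y_iq = 1` if `Z_iq < eta_iq`, so a larger linear predictor gives
#' a higher case probability and the marginal prevalence under the null
#' (`eta = 0`) is 0.5 (liability-threshold construction).
#'
#' @param eta N x Q matrix of latent linear predictors.
#' @param rho exchangeable latent correlation in `[0, 1)`.
#' @param seed RNG seed.
#' @return N x Q binary matrix.
#' @export
simulate_phenotypes <- function(eta, rho, seed = 1) {
  eta <- as.matrix(eta)
  N <- nrow(eta); Q <- ncol(eta)
  stopifnot(rho >= 0, rho < 1)
  Sigma <- matrix(rho, Q, Q); diag(Sigma) <- 1
  with_seed(seed, {
    Z <- if (Q == 1) matrix(stats::rnorm(N), N, 1) else
      MASS::mvrnorm(N, mu = rep(0, Q), Sigma = Sigma)
    (Z < eta) * 1
  })
}

#' Simulate one complete replicate
#'
#' Variant pool, latent predictors, and thresholded binary phenotypes,
#' with truth labels for the causal pathway and genes.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (pool and phenotypes use derived sub-seeds).
#' @return list with `genotypes`, `annotation`, `Y`, `eta`, `truth`
#'   (list: causal_pathway, causal_genes) and `variants`.
#' @export
simulate_replicate <- function(config, seed = 1) {
  pool <- simulate_variant_pool(config, seed = seed)
  eta <- simulate_linear_predictor(pool, config)
  Y <- simulate_phenotypes(eta, config$rho, seed = seed + 500000L)
  colnames(Y) <- paste0("Y", seq_len(config$Q))
  list(genotypes = pool$genotypes, annotation = pool$annotation,
       Y = Y, eta = eta,
       truth = list(causal_pathway = "P1",
                    causal_genes = if (config$H1 > 0)
                      paste0("G", seq_len(config$H1)) else character(0)),
       variants = pool$variants)
}

#' Type-I-error / power study harness
#'
#' Runs the full pipeline (simulate, collapse, fit, permutation-test all
#' pathways jointly, BH-adjust) over `n_replicates` replicates of one
#' study condition and summarizes: empirical power (fraction of
#' replicates where the causal pathway is discovered at BH level
#' `fdr_level`), empirical type-I error (fraction of non-causal pathway
#' tests with `p < alpha_level`), and empirical FDR among BH discoveries.
#' Discovery uses the standard step-up rule `q <= fdr_level`.
#'
#' @param config a [sim_config()].
#' @param n_replicates number of replicates (default 50).
#' @param n_perm permutations per replicate (default 199).
#' @param lambda_G,lambda_P penalties for every fit (held fixed; default 1).
#' @param corstr working correlation (default `"exchangeable"`).
#' @param alpha_level type-I-error significance level (default 0.01).
#' @param fdr_level BH control level (default 0.05).
#' @param seed base seed; replicate r uses `seed + r` for its data and
#'   `seed + 1000 + r` for its permutations.
#' @return an object of class `pharaoh_study`: list with `summary` (one-row
#'   data frame: power, type1_error, fdr, n_replicates, n_failed),
#'   `p_matrix`, `q_matrix` (replicates x K), `config`, settings.
#' @export
run_study <- function(config, n_replicates = 50, n_perm = 199,
                      lambda_G = 1, lambda_P = 1,
                      corstr = "exchangeable",
                      alpha_level = 0.01, fdr_level = 0.05, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$K
  p_mat <- matrix(NA_real_, n_replicates, K)
  q_mat <- matrix(NA_real_, n_replicates, K)
  failed <- 0L
  for (r in seq_len(n_replicates)) {
    res <- tryCatch(suppressWarnings({
      rep_data <- simulate_replicate(config, seed = seed + r)
      design <- build_design(rep_data$genotypes, rep_data$annotation)
      pt <- pharaoh_perm_test(design, rep_data$Y,
                              lambda_G = lambda_G, lambda_P = lambda_P,
                              family = "binomial", corstr = corstr,
                              n_perm = n_perm, seed = seed + 1000L + r,
                              force = TRUE)
      # align to the configured pathway order (pathways can be dropped)
      p <- q <- rep(NA_real_, K)
      i <- match(pt$pathways$pathway, paste0("P", seq_len(K)))
      p[i] <- pt$pathways$p
      q[i] <- bh_fdr(pt$pathways$p)
      list(p = p, q = q)
    }), error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    p_mat[r, ] <- res$p
    q_mat[r, ] <- res$q
  }
  used <- which(!is.na(p_mat[, 1]))
  if (length(used) == 0) stop("all study replicates failed")
  null_p <- p_mat[used, -1, drop = FALSE]
  type1 <- mean(null_p < alpha_level, na.rm = TRUE)
  power <- mean(q_mat[used, 1] <= fdr_level, na.rm = TRUE)
  # FDR = E[V / max(R, 1)]: per-replicate false discovery proportion among
  # BH discoveries (0 when nothing is discovered), averaged over replicates
  # -- the quantity the BH step-up controls
  fdp <- apply(q_mat[used, , drop = FALSE], 1, function(q) {
    disc <- which(q <= fdr_level)
    if (length(disc) == 0) return(0)
    sum(disc != 1) / length(disc)
  })
  fdr <- mean(fdp)
  summary <- data.frame(power = power, type1_error = type1, fdr = fdr,
                        n_replicates = length(used), n_failed = failed,
                        alpha_level = alpha_level, fdr_level = fdr_level)
  structure(list(summary = summary, p_matrix = p_mat, q_matrix = q_mat,
                 config = config, n_perm = n_perm,
                 lambda_G = lambda_G, lambda_P = lambda_P,
                 corstr = corstr, seed = seed),
            class = "pharaoh_study")
}

#' @exportS3Method base::print
print.pharaoh_study <- function(x, ...) {
  cfg <- x$config
  cat("Simulation study: ", x$summary$n_replicates, " replicates, N = ",
      cfg$N, ", K = ", cfg$K, ", w = ", cfg$w, ", beta = ", cfg$beta,
      ", H1 = ", cfg$H1, ", rho = ", cfg$rho, "\n", sep = "")
  cat(sprintf("  power (BH q <= %.2f):      %.3f\n",
              x$summary$fdr_level, x$summary$power))
  cat(sprintf("  type-I error (p < %.2f):   %.4f\n",
              x$summary$alpha_level, x$summary$type1_error))
  cat(sprintf("  empirical FDR:             %.3f\n", x$summary$fdr))
  invisible(x)
}
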