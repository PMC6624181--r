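test_that("variant weights are |log10 MAF| and reject invalid frequencies", {
  expect_equal(variant_weights(0.01), 2)
  expect_equal(variant_weights(c(0.1, 0.001)), c(1, 3))
  expect_equal(variant_weights(0.5), abs(log10(0.5)))
  expect_error(variant_weights(0), "invalid frequency")
  expect_error(variant_weights(0.6), "invalid frequency")
  expect_error(variant_weights(-0.1), "invalid frequency")
})

test_that("gene collapsing is the weighted dosage sum", {
  expect_equal(collapse_gene(matrix(c(0, 1, 2), 3), 1), c(0, 1, 2))
  expect_equal(collapse_gene(matrix(c(1, 0, 1, 2), 2), c(2, 0.5)),
               c(2.5, 1))
  # brute-force double loop on random dosages
  set.seed(42)
  maf <- c(0.01, 0.02, 0.005)
  dos <- matrix(rbinom(30, 2, rep(maf, each = 10)), 10)
  wts <- variant_weights(maf)
  expected <- numeric(10)
  for (i in 1:10)
    for (j in 1:3)
      expected[i] <- expected[i] + wts[j] * dos[i, j]
  expect_equal(collapse_gene(dos, wts), expected)
})

test_that("collapsing is linear in dosages and sample-order equivariant", {
  set.seed(7)
  A <- matrix(rbinom(40, 1, 0.3), 10)
  B <- matrix(rbinom(40, 1, 0.3), 10)
  wts <- runif(4)
  expect_equal(collapse_gene(A + B, wts),
               collapse_gene(A, wts) + collapse_gene(B, wts))
  perm <- sample(10)
  expect_equal(collapse_gene(A[perm, ], wts), collapse_gene(A, wts)[perm])
})

test_that("missing dosages are mean-imputed and all-missing columns dropped", {
  dos <- matrix(c(0, 2, NA, 1, 1, 1), 3)
  out <- collapse_gene(dos, c(1, 1))
  expect_equal(out, c(0 + 1, 2 + 1, 1 + 1))  # NA -> mean(0,2) = 1
  dos2 <- cbind(c(1, 0, 1), NA)
  expect_warning(out2 <- collapse_gene(dos2, c(1, 1)), "all-missing")
  expect_equal(out2, c(1, 0, 1))
})

test_that("standardization gives diag(X'X) = N I and leaves the intercept", {
  expect_equal(standardize_design(cbind(1, c(1, -1, 1, -1)))$X[, 2],
               c(1, -1, 1, -1))
  expect_equal(standardize_design(cbind(1, c(2, -2, 2, -2)))$X[, 2],
               c(1, -1, 1, -1))
  set.seed(3)
  d <- tiny_design(N = 17, Tk = c(3, 2, 4), seed = 3)
  N <- nrow(d$X)
  expect_true(all(d$X[, 1] == 1))
  expect_equal(unname(colSums(d$X^2)), rep(N, ncol(d$X)), tolerance = 1e-10)
  expect_equal(unname(colSums(d$X[, -1, drop = FALSE])),
               rep(0, ncol(d$X) - 1), tolerance = 1e-10)
})

test_that("zero-variance gene columns are dropped with a warning", {
  X_raw <- cbind(1, rnorm(10), rep(2, 10))
  expect_warning(d <- standardize_design(X_raw), "zero-variance")
  expect_equal(ncol(d$X), 2)
  expect_error(suppressWarnings(standardize_design(cbind(1, rep(1, 5)))),
               "no informative gene")
})

test_that("build_design assembles pathway-major standardized burdens", {
  tg <- tiny_genotypes(seed = 11, N = 30, K = 2, genes_per_pathway = 1)
  d <- build_design(tg$genotypes, tg$annotation)
  expect_s3_class(d, "pharaoh_design")
  expect_equal(dim(d$X), c(30, 3))
  expect_true(all(d$X[, 1] == 1))
  expect_equal(d$K, 2)
  expect_equal(d$block$pathway, c("P1", "P2"))
  # standardization constraint propagates through the full builder
  expect_equal(unname(colSums(d$X^2)), rep(30, 3), tolerance = 1e-8)
})

test_that("a gene shared by two pathways is duplicated per membership", {
  tg <- tiny_genotypes(seed = 5, N = 25, K = 1, genes_per_pathway = 2)
  annot <- pathway_annotation(tg$v2g, list(P1 = c("G1", "G2"),
                                           P2 = c("G1")))
  d <- build_design(tg$genotypes, annot)
  expect_equal(nrow(d$block), 3)
  i1 <- which(d$block$gene == "G1")
  expect_length(i1, 2)
  expect_equal(d$X_raw[, i1[1] + 1], d$X_raw[, i1[2] + 1])
})

test_that("MAF filter excludes common variants from the burdens", {
  tg <- tiny_genotypes(seed = 9, N = 60, K = 1, genes_per_pathway = 2,
                       maf = c(0.01, 0.3, 0.02, 0.01, 0.02, 0.04))
  d5 <- build_design(tg$genotypes, tg$annotation, maf_threshold = 0.05)
  # gene 1 burden must ignore variant 2 (MAF 0.3)
  wts <- variant_weights(c(0.01, 0.02))
  manual <- collapse_gene(tg$genotypes$dosages[, c(1, 3)], wts)
  expect_equal(unname(d5$X_raw[, 2]), unname(manual))
})

test_that("pathways with no usable gene are dropped with a warning", {
  tg <- tiny_genotypes(seed = 13, N = 30, K = 2, genes_per_pathway = 1)
  annot <- pathway_annotation(tg$v2g,
                              list(P1 = "G1", P2 = "G2", P9 = "NO_SUCH"))
  expect_warning(d <- build_design(tg$genotypes, annot), "P9")
  expect_equal(d$K, 2)
  expect_equal(d$pathways, c("P1", "P2"))
})

test_that("the simulated study design yields 10 x 10 gene columns", {
  cfg <- sim_config(N = 300, K = 10, genes_per_pathway = 10)
  pool <- simulate_variant_pool(cfg, seed = 21)
  d <- build_design(pool$genotypes, pool$annotation)
  expect_equal(d$K, 10)
  expect_equal(nrow(d$block), 100)
  expect_equal(ncol(d$X), 101)
})
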