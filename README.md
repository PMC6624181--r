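# pharaohgee

Pathway-level association testing of **rare variants** against
**clustered phenotypes** — repeated measurements or panels of correlated
traits — using a doubly ridge-penalized hierarchical structured-component
model estimated by generalized estimating equations (GEE), with
permutation-based inference.

## Who this is for

Statistical geneticists analyzing sequencing studies in which (i) single
rare variants are too sparse to test individually and (ii) several
correlated outcomes were measured per individual (e.g. the binary
components of the metabolic syndrome). Instead of running one pathway at
a time against one phenotype at a time, all pathways and all phenotypes
enter a single model, so inter-pathway correlation is controlled and each
pathway gets one joint test against the whole phenotype vector.

## The model

Rare variants (MAF ≤ 0.05) are collapsed into gene burdens with weights
|log10 MAF|; burdens are standardized to `diag(X'X) = N·I`. For
individual *i*, phenotype *q*:

```
g(mu_iq) = beta_0q + sum_k f_ik * beta_kq ,    f_ik = sum_t x_ikt * w_tk
```

with latent pathway components `f_ik` (weights **W**, block-sparse) and
pathway-to-phenotype coefficients **B**. The within-individual covariance
is `Sigma_i = phi * A^1/2 R(alpha) A^1/2` with a working correlation `R`
(independence / exchangeable / AR-1 / unstructured). **W** and **B** are
estimated by alternating closed-form ridge-GLS solves with separate
penalties `lambda_G` (gene→pathway) and `lambda_P` (pathway→phenotype),
selected by k-fold cross-validation on predictive quasi-deviance.
Pathway *k* is tested jointly across the Q phenotypes with a Wald-type
statistic `T = beta_k' cov^-1(beta_k) beta_k`, calibrated by permuting
whole phenotype rows and refitting; BH q-values and Westfall–Young max-T
adjusted p-values handle multiplicity. See the methods vignette
(`vignettes/pathway-gee-methods.Rmd`) for the estimation algorithm,
numerical choices and the simulator design.

## Worked example

Simulate a small study (three pathways, pathway 1 causal through its
first two genes), collapse, and test:

```r
library(pharaohgee)

cfg  <- sim_config(N = 400, K = 3, genes_per_pathway = 4, H1 = 2,
                   w = 1, beta = 0.4, rho = 0.25, Q = 3)
rep1 <- simulate_replicate(cfg, seed = 7)

design <- build_design(rep1$genotypes, rep1$annotation)
design
#> pharaoh_design: 400 samples, 3 pathways, 12 gene columns
#>   genes per pathway: 4, 4, 4

test <- pharaoh_perm_test(design, rep1$Y, lambda_G = 1, lambda_P = 1,
                          family = "binomial", corstr = "exchangeable",
                          n_perm = 499, seed = 7)
test
#> Permutation pathway test (499 permutations)
#>  pathway       T     p     q  wy_p
#>       P1 5.92935 0.032 0.096 0.036
#>       P2 1.67175 0.966 0.966 1.000
#>       P3 2.78418 0.582 0.873 0.906
```

The causal pathway P1 has the largest Wald statistic and a permutation
p-value of 0.032: its observed joint effect across the three binary
phenotypes exceeded all but 15 of 499 phenotype-permuted refits. `q` is
the BH-adjusted value over the three pathways and `wy_p` the max-T
family-wise adjusted p-value. Gene-level tests from the same permutation
pass rank the truly causal gene first:

```r
head(test$genes[order(test$genes$p), ], 3)
#>    gene pathway          w     p     q
#> 1    G1      P1  0.7346535 0.004 0.048
#> 12  G12      P3  0.4577149 0.072 0.432
#> 2    G2      P1  0.4283082 0.158 0.632
```

Real data enter through files instead of the simulator: a dosage TSV or
VCF, a variant→gene map, a GMT pathway file and a phenotype TSV, wired
together by `run_pipeline()` (or the CLI in `inst/cli/pharaoh-gee.R`,
with subcommands `simulate | cv | fit | test | study`).

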