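---
title: "Pathway tests for rare variants with clustered phenotypes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway tests for rare variants with clustered phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharaohgee)
```

## The problem

Rare-variant association studies face two compounding power problems:
individual rare variants are too sparse to test, and single phenotypes
carry limited information when a study has measured several correlated
outcomes (repeated measurements, or a panel of related traits such as the
components of the metabolic syndrome). `pharaohgee` addresses both at
once. Rare variants are collapsed into gene-level burden scores, genes are
aggregated into latent pathway components, and all pathways are linked to
all phenotypes jointly in a single marginal model fitted by generalized
estimating equations (GEE). Because every pathway sits in one model, the
correlation between pathways (shared genes, correlated burdens) is
adjusted for rather than ignored, and a joint Wald-type test asks whether
a pathway is associated with *any* of the clustered phenotypes.

## The model

For individual $i$ with phenotype vector
$\tilde y_i = (y_{i1},\dots,y_{iQ})'$, each $y_{iq}$ follows an
exponential-family marginal with mean $\mu_{iq}$ and

$$g(\mu_{iq}) = \eta_{iq} = \beta_{0q} + \sum_{k=1}^{K} f_{ik}\,\beta_{kq},
\qquad f_{ik} = \sum_{t=1}^{T_k} x_{ikt}\, w_{tk},$$

where $x_{ikt}$ is the standardized burden of gene $t$ in pathway $k$,
$w_{tk}$ the gene-to-pathway weight and $\beta_{kq}$ the
pathway-to-phenotype coefficient — the hierarchical structured-component
(GSCA) construction. Within-individual covariance is modeled as
$\Sigma_i = \varphi A_i^{1/2} R(\alpha) A_i^{1/2}$ with variance function
$A_i = \mathrm{diag}\,\nu(\mu_{iq})$ and a working correlation $R(\alpha)$
(independence, exchangeable, AR-1 or unstructured). GEE point estimates
remain consistent when $R$ is misspecified; a test in the suite verifies
the product $w\beta$ is recovered under an independence working
correlation on exchangeable-correlated data.

### Collapsing and standardization

A variant with minor allele frequency $\mathrm{MAF}_j \le 0.05$ (the
configurable rare-variant threshold) contributes to its gene's burden with
weight $|\log_{10}\mathrm{MAF}_j|$, so rarer variants weigh more; a
uniform-weight option exists. Missing dosages are mean-imputed per
variant, the standard practice for burden scores. A gene annotated to
several pathways is duplicated as one column per membership, because the
block structure of the weight matrix forbids shared columns. The design
matrix (intercept plus the $T$ burdens, pathway-major) is standardized to
the GSCA scaling constraint $\mathrm{diag}(X'X) = N I$. We mean-center
before rescaling so that components are orthogonal to the intercept and
the intercept stays interpretable; the constraint itself only fixes the
column scale.

### Estimation

Both levels of the hierarchy are ridge-penalized — $\lambda_G$ on the
weights, $\lambda_P$ on the coefficients (intercepts unpenalized, the
usual ridge convention) — which controls the strong collinearity among
genes and among pathways. Estimation alternates closed-form penalized
generalized-least-squares solves:

1. **Coefficients**: with $Q_i = f_i' \otimes I_Q$,
   $\hat b = \big(\sum_i Q_i' V_i^{-1} Q_i + \lambda_P D\big)^{-1}
   \sum_i Q_i' V_i^{-1} z_i$;
2. **Weights**: with $M_i$ the columns of $x_i' \otimes B'$ belonging to
   structurally nonzero weights and the intercept moved to an offset,
   $\hat w = \big(\sum_i M_i' V_i^{-1} M_i + \lambda_G I\big)^{-1}
   \sum_i M_i' V_i^{-1} (z_i - \beta_0)$;
3. **Nuisance**: Pearson residuals
   $r_{ij} = (y_{ij}-\hat\mu_{ij})/\nu^{1/2}(\hat\mu_{ij})$ update the
   working correlation by moment estimators and the dispersion by
   $\hat\varphi = \big(NQ - (K + \textstyle\sum_k T_k)\big)^{-1}
   \sum_{ij} \hat r_{ij}^2$.

For binomial phenotypes the response in steps 1–2 is the standard GEE
working response $z = \eta + (y-\mu)\,g'(\mu)$ with the Fisher-scoring
cluster weight $V_i^{-1} = A_i^{1/2}R^{-1}A_i^{1/2}/\varphi$; for
gaussian/identity these reduce to $z = y$ and $V_i = \varphi R$. The
dispersion is fixed at 1 for binary phenotypes by default (standard GEE
practice) and estimable behind a flag. The alternation stops when the
largest absolute change in the free parameters falls below `tol` (default
`1e-5`, at most 200 iterations); non-convergence returns the iterate with
the best penalized quasi-deviance, flagged `converged = FALSE`.

### Numerical choices

Three numerical devices matter in practice and change nothing about the
estimator, only the path to it:

* **Ridge-balanced rescaling.** The linear predictor is invariant under
  $(w_k c,\ \beta_k/c)$, and at any fixed point of the alternation the
  penalties balance: $\lambda_G\|w_k\|^2 = \lambda_P\|\beta_k\|^2$. Each
  iteration jumps straight to that balanced scale — a no-op at the fixed
  point that removes the slowest drift direction.
* **Safeguarded Anderson mixing** (depth 3, coefficient cap) accelerates
  the remaining linearly contracting modes, which can be slow (contraction
  rates up to about 0.95) on null-like data where component directions are
  weakly identified.
* **Compiled path.** The full iteration is implemented in
  RcppArmadillo; a pure-R loop with identical numerics is kept as the
  reference (`options(pharaohgee.engine = FALSE)`) and the suite asserts
  the two agree to machine precision. Permutation testing refits the
  model hundreds of times per dataset, which is why this matters.

Sign indeterminacy is resolved after convergence by flipping each
pathway's weight block (and its coefficient row jointly) so the
largest-magnitude weight is positive. Component scores are *not*
re-standardized within iterations — only the design columns are
standardized, and the two ridge penalties control the component scale; a
flag (`standardize_components`) enables the alternative GSCA convention.
Binomial means are clamped to $[10^{-8}, 1-10^{-8}]$; a non-positive-definite
unstructured correlation estimate is repaired by an eigenvalue floor at
$10^{-6}$ followed by rescaling to unit diagonal.

## Penalty selection

`pharaoh_cv()` evaluates a two-dimensional grid (default
$\lambda \in \{0.01, 0.1, 1, 10, 100\}$ per axis, $k = 5$ folds) by
unpenalized predictive quasi-deviance on held-out folds
(gaussian: $\sum(y-\mu)^2$; binomial:
$2\sum[y\log(y/\mu) + (1-y)\log((1-y)/(1-\mu))]$). Standardization is
recomputed inside each training fold and applied with training statistics
to the held-out fold, so no holdout information leaks into the fit; ties
break toward the more regularized cell. One caveat worth knowing: because
of the $(w c, \beta/c)$ indeterminacy the two penalties partially trade
off — prediction pins down mainly their combination — so the selected
pair should be read as "an amount of regularization", not as separately
meaningful values.

## Inference

Significance comes from permutations: whole phenotype rows $\tilde y_i$
are permuted across individuals — never within a row — so the
within-cluster correlation is preserved under the null, and the model is
refitted per permutation with the penalties held fixed (re-running CV
inside every permutation would be computationally prohibitive; holding
$\lambda$ fixed is a documented approximation). Each pathway is tested
with the Wald-type statistic $T_k = \tilde\beta_k'\,
\mathrm{cov}^{-1}(\tilde\beta_k)\,\tilde\beta_k$, with the covariance
taken, by default, as the sample covariance of the permuted coefficient
vectors (the cheap "indirect" estimate; the direct penalized-GEE sandwich
is available via `cov_method = "sandwich"`). p-values use the add-one
rule $p = (1 + \#\{T^{\mathrm{null}} \ge T^{\mathrm{obs}}\})/(B+1)$ and
are never zero. Gene-level p-values are two-sided quantiles of each
weight against its permutation null, with the sign convention applied to
every permuted fit so weight signs are comparable. Benjamini–Hochberg
q-values and Westfall–Young max-T family-wise adjusted p-values are
reported; with a single pathway the max-T adjustment collapses to the raw
permutation p, and it always dominates it.

On the sandwich covariance: the published form of the penalty term in the
bread is a scalar trace where a matrix is required; this package uses the
ridge contribution $\lambda_P D$ (the same matrix the coefficient update
adds), which makes the bread exactly the update's left-hand side and
reduces to the classical GEE sandwich when $\lambda_P = 0$. The covariance
is computed on the component-score design — the design the coefficients
are actually regressed on.

## The simulator and the study harness

`simulate_variant_pool()` draws, per gene, a number of rare variants
uniform on a range (default 5–20) with MAFs log-uniform on
$[10^{-4}, 0.01]$ and genotypes $\mathrm{Binomial}(2, \mathrm{MAF})$
under Hardy–Weinberg equilibrium. This reproduces the statistical
structure a rare-variant study needs — a rare, skewed frequency spectrum
with Hardy-Weinberg genotypes — not the coalescent detail of
population-genetic simulators, so *absolute* power numbers are specific
to this pool and only orderings across effect sizes are meaningful
claims. Only pathway 1 is causal: its first $H_1$ genes contribute

$$\eta_{iq} = \beta \sum_{t \le H_1} w \sum_j |\log_{10}\mathrm{MAF}_{tj}|\,
g_{itj},$$

with the same $\beta$ for all $Q$ phenotypes (effects are reported as
single values per setting, so a shared coefficient is the faithful
reading). Binary phenotypes are generated by liability thresholding:
$Z_i \sim \mathrm{MVN}(0, \Sigma_\rho)$ with exchangeable latent
correlation $\rho$, and $y_{iq} = 1$ if $Z_{iq} < \eta_{iq}$ — so larger
$\eta$ means higher case probability and the null prevalence is exactly
0.5. The number of phenotypes defaults to $Q = 3$, a typical clustered
panel size. What the generator does *not* emulate: linkage disequilibrium
between variants, population structure, covariates, missing phenotypes,
and realistic case-control ascertainment — passing tests say nothing
about robustness to those.

`run_study()` runs the full pipeline per replicate (simulate, collapse,
fit, permutation-test all $K$ pathways jointly, BH-adjust) and reports
empirical power ($q \le 0.05$ for the causal pathway; the standard BH
step-up rejection rule), type-I error ($p < \alpha$ among the $K-1$
non-causal pathways) and empirical FDR, defined as
$\mathbb{E}[V/\max(R,1)]$ over replicates — the quantity the BH procedure
controls, with replicates lacking any discovery contributing 0. The
study defaults used by the acceptance checks are deliberately desk-scale:
50 replicates of $N = 500$ with 199 permutations for calibration
quantities, and a 5-pathway/5-gene grid with 25 replicates per setting
for the power-ordering checks; null-uniformity checks use 100 replicates
of a small 3-pathway null model. Penalties are held at
$\lambda_G = \lambda_P = 1$ throughout the harness — a mid-grid value —
because re-selecting penalties inside every replicate and permutation is
not informative for calibration and multiplies cost.

With 199 permutations the attainable p-value floor is $1/200 = 0.005$;
over $K = 10$ pathways the smallest attainable q-value is exactly 0.05,
which is why discovery uses the standard non-strict rule $q \le 0.05$.
At $\alpha = 0.01$ the permutation test is conservative by construction
(rejection requires the observed statistic to beat all 199 null
statistics, an event of null probability 0.005), which the type-I-error
check reflects.

## Known limitations

* Gaussian and binomial families only; count phenotypes would need a new
  variance function and link but no new architecture.
* Complete cases only — unbalanced clusters (missing phenotype entries)
  are not modeled.
* No variant-level QC: call-rate and HWE filtering are assumed done
  upstream.
* Penalties fixed across permutations (see above).
* The permutation covariance requires enough permutations ($\ge Q + 2$;
  in practice hundreds) to be stable; with very few permutations the
  Wald statistic degrades.
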