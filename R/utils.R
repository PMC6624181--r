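#' @useDynLib pharaohgee, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats plogis qlogis rbinom runif sd var cov p.adjust
NULL

.EPS_MU <- 1e-8

clamp_mu <- function(mu, family, warn = FALSE) {
  if (family == "binomial") {
    out <- mu < .EPS_MU | mu > 1 - .EPS_MU
    if (any(out)) {
      if (warn) warning("binomial means at the boundary clamped to [",
                        .EPS_MU, ", 1 - ", .EPS_MU, "]")
      mu <- pmin(pmax(mu, .EPS_MU), 1 - .EPS_MU)
    }
  }
  mu
}

check_family <- function(family) {
  match.arg(family, c("gaussian", "binomial"))
}

check_corstr <- function(structure) {
  match.arg(structure, c("independence", "exchangeable", "ar1", "unstructured"))
}

#' Variance function of the response family
#'
#' Returns `nu(mu)`: identically 1 for the gaussian family and
#' `mu * (1 - mu)` for the binomial family.
#'
#' @param mu numeric vector or matrix of means.
#' @param family `"gaussian"` or `"binomial"`.
#' @return object shaped like `mu` with the variance-function values.
#' @keywords internal
variance_function <- function(mu, family) {
  family <- check_family(family)
  if (family == "gaussian") {
    mu[] <- 1
    mu
  } else {
    mu <- clamp_mu(mu, family)
    mu * (1 - mu)
  }
}

linkinv_fun <- function(eta, family) {
  if (family == "gaussian") eta else plogis(eta)
}

link_fun <- function(mu, family) {
  if (family == "gaussian") mu else qlogis(clamp_mu(mu, family))
}

as_phenotype_matrix <- function(Y) {
  if (is.data.frame(Y)) Y <- as.matrix(Y)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  if (!is.matrix(Y) || !is.numeric(Y))
    stop("phenotypes must be a numeric matrix, data frame or vector")
  if (anyNA(Y))
    stop("phenotypes contain missing values; only complete cases are supported")
  Y
}

check_binary <- function(Y) {
  if (!all(Y %in% c(0, 1)))
    stop("binomial family requires phenotype values in {0, 1}")
  invisible(TRUE)
}
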