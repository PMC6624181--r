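#' Genotype dosage container
#'
#' Bundles a sample-by-variant matrix of allele counts with sample and
#' variant identifiers and per-variant minor allele frequencies (MAF).
#' Dosages must lie in \{0, 1, 2\} (missing values allowed). If `maf` is not
#' supplied it is estimated from the observed dosages and folded onto
#' (0, 0.5].
#'
#' @param dosages numeric N x V matrix of allele counts.
#' @param sample_ids character vector of length N (defaults to rownames).
#' @param variant_ids character vector of length V (defaults to colnames).
#' @param maf optional numeric vector of length V of minor allele frequencies.
#' @return an object of class `genotype_matrix` with elements `dosages`,
#'   `sample_ids`, `variant_ids`, `maf`.
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, variant_ids = NULL,
                            maf = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 2 || ncol(dosages) < 1)
    stop("need at least 2 samples and 1 variant")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok))
    stop("dosages must be 0, 1, 2 or missing")
  if (is.null(sample_ids))
    sample_ids <- rownames(dosages) %||% paste0("S", seq_len(nrow(dosages)))
  if (is.null(variant_ids))
    variant_ids <- colnames(dosages) %||% paste0("V", seq_len(ncol(dosages)))
  stopifnot(length(sample_ids) == nrow(dosages),
            length(variant_ids) == ncol(dosages))
  if (is.null(maf)) {
    p <- colMeans(dosages, na.rm = TRUE) / 2
    p[is.nan(p)] <- 0
    maf <- pmin(p, 1 - p)
  }
  stopifnot(length(maf) == ncol(dosages))
  dimnames(dosages) <- list(sample_ids, variant_ids)
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 variant_ids = variant_ids, maf = as.numeric(maf)),
            class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      length(x$variant_ids), "variants\n")
  cat("  MAF range:", format(range(x$maf), digits = 3), "\n")
  invisible(x)
}

#' Variant-to-gene and gene-to-pathway annotation
#'
#' @param variant_to_gene named character vector (names = variant ids,
#'   values = gene ids) or a two-column data frame `(variant, gene)`.
#' @param gene_to_pathways named list mapping pathway id to a character
#'   vector of member genes (the GMT structure, see [read_gmt()]). The list
#'   order defines the pathway order; gene order within each pathway is kept.
#' @return an object of class `pathway_annotation`.
#' @export
pathway_annotation <- function(variant_to_gene, gene_to_pathways) {
  if (is.data.frame(variant_to_gene)) {
    v2g <- as.character(variant_to_gene[[2]])
    names(v2g) <- as.character(variant_to_gene[[1]])
  } else {
    v2g <- variant_to_gene
  }
  if (is.null(names(v2g)) || anyNA(names(v2g)))
    stop("variant_to_gene must be named by variant id")
  if (!is.list(gene_to_pathways) || is.null(names(gene_to_pathways)))
    stop("gene_to_pathways must be a named list of gene vectors")
  if (anyDuplicated(names(gene_to_pathways)))
    stop("duplicate pathway ids in annotation")
  structure(list(variant_to_gene = v2g,
                 pathways = lapply(gene_to_pathways, as.character)),
            class = "pathway_annotation")
}

#' @exportS3Method base::print
print.pathway_annotation <- function(x, ...) {
  cat("pathway_annotation:", length(x$pathways), "pathways,",
      length(unique(x$variant_to_gene)), "genes,",
      length(x$variant_to_gene), "mapped variants\n")
  invisible(x)
}

#' MAF-based collapsing weights
#'
#' Per-variant weight `|log10(MAF)|`, so rarer variants receive larger
#' weights in the gene burden.
#'
#' @param maf numeric vector of minor allele frequencies in (0, 0.5].
#' @return non-negative numeric vector of weights.
#' @export
#' @examples
#' variant_weights(c(0.01, 0.1)) # 2, 1
variant_weights <- function(maf) {
  if (!is.numeric(maf) || any(maf <= 0) || any(maf > 0.5))
    stop("invalid frequency: MAF must lie in (0, 0.5]")
  abs(log10(maf))
}

#' Collapse one gene's variants into a weighted burden score
#'
#' Burden of sample i is `sum_j weights_j * dosage_ij`. Missing dosages are
#' mean-imputed per variant; variants missing in every sample are dropped
#' with a warning.
#'
#' @param dosages N x m matrix of allele counts for the gene's variants.
#' @param weights non-negative numeric vector of length m.
#' @return numeric burden vector of length N.
#' @export
collapse_gene <- function(dosages, weights) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(weights))
    stop("one weight per variant required")
  if (any(weights < 0)) stop("weights must be non-negative")
  all_na <- colSums(!is.na(dosages)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " all-missing variant column(s) dropped")
    dosages <- dosages[, !all_na, drop = FALSE]
    weights <- weights[!all_na]
    if (ncol(dosages) == 0) return(numeric(nrow(dosages)))
  }
  if (anyNA(dosages)) {
    mns <- colMeans(dosages, na.rm = TRUE)
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- mns[idx[, 2]]
  }
  drop(dosages %*% weights)
}

#' Build the standardized gene-level collapsed design matrix
#'
#' Filters variants to those with `0 < MAF <= maf_threshold`, collapses each
#' gene's variants into a weighted burden (see [collapse_gene()]), arranges
#' the burdens pathway-major (a gene belonging to several pathways is
#' duplicated as one column per membership), prepends an intercept column
#' and standardizes via [standardize_design()] so that
#' `diag(X'X) = N * I`.
#'
#' Genes with no retained variant are skipped; pathways with no usable gene
#' are dropped with a warning; an empty result is an error.
#'
#' @param genotypes a [genotype_matrix()].
#' @param annotation a [pathway_annotation()].
#' @param maf_threshold rare-variant inclusion threshold (default 0.05).
#' @param weight_fun `"log_maf"` for `|log10 MAF|` weights (default) or
#'   `"uniform"` for unit weights.
#' @return an object of class `pharaoh_design`; see [standardize_design()].
#' @export
build_design <- function(genotypes, annotation, maf_threshold = 0.05,
                         weight_fun = c("log_maf", "uniform")) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(annotation, "pathway_annotation"))
  weight_fun <- match.arg(weight_fun)
  keep <- genotypes$maf > 0 & genotypes$maf <= maf_threshold
  if (!any(keep)) stop("no variants pass the MAF filter")
  vids <- genotypes$variant_ids[keep]
  maf <- genotypes$maf[keep]
  dos <- genotypes$dosages[, keep, drop = FALSE]
  gene_of <- annotation$variant_to_gene[vids]

  N <- nrow(dos)
  cols <- list(); blk_pathway <- character(); blk_gene <- character()
  blk_k <- integer()
  k <- 0L
  kept_pathways <- character()
  for (pw in names(annotation$pathways)) {
    genes <- annotation$pathways[[pw]]
    pw_cols <- list(); pw_genes <- character()
    for (g in genes) {
      j <- which(!is.na(gene_of) & gene_of == g)
      if (length(j) == 0) next
      w <- if (weight_fun == "log_maf") variant_weights(maf[j]) else
        rep(1, length(j))
      pw_cols[[length(pw_cols) + 1L]] <- collapse_gene(dos[, j, drop = FALSE], w)
      pw_genes <- c(pw_genes, g)
    }
    if (length(pw_cols) == 0) {
      warning("pathway '", pw, "' has no usable gene; dropped")
      next
    }
    k <- k + 1L
    kept_pathways <- c(kept_pathways, pw)
    cols <- c(cols, pw_cols)
    blk_pathway <- c(blk_pathway, rep(pw, length(pw_cols)))
    blk_gene <- c(blk_gene, pw_genes)
    blk_k <- c(blk_k, rep(k, length(pw_cols)))
  }
  if (k == 0L) stop("no pathway has any usable gene after filtering")
  X_raw <- cbind(1, do.call(cbind, cols))
  colnames(X_raw) <- c("(Intercept)", paste(blk_pathway, blk_gene, sep = ":"))
  rownames(X_raw) <- genotypes$sample_ids
  block <- data.frame(k = blk_k, pathway = blk_pathway, gene = blk_gene,
                      stringsAsFactors = FALSE)
  standardize_design(X_raw, block = block, pathways = kept_pathways)
}

#' Standardize a collapsed design matrix
#'
#' Mean-centers each non-intercept column and rescales it so its sum of
#' squares equals N, giving the scaling constraint `diag(X'X) = N * I`.
#' The intercept column is untouched. Zero-variance columns carry no
#' information and are dropped with a warning.
#'
#' @param X_raw N x (T+1) matrix whose first column is all ones.
#' @param block optional data frame with one row per non-intercept column
#'   and columns `k` (1-based pathway index), `pathway`, `gene`.
#' @param pathways optional character vector of pathway ids in order.
#' @return an object of class `pharaoh_design` with elements `X`
#'   (standardized), `X_raw`, `block`, `N`, `K`, `Tk` (genes per pathway),
#'   `pathways`, `center`, `scale`.
#' @export
standardize_design <- function(X_raw, block = NULL, pathways = NULL) {
  X_raw <- as.matrix(X_raw)
  N <- nrow(X_raw)
  if (any(X_raw[, 1] != 1)) stop("first column must be the intercept (all 1)")
  T_all <- ncol(X_raw) - 1L
  if (is.null(block)) {
    block <- data.frame(k = rep(1L, T_all),
                        pathway = rep("P1", T_all),
                        gene = colnames(X_raw)[-1] %||% paste0("G", seq_len(T_all)),
                        stringsAsFactors = FALSE)
  }
  stopifnot(nrow(block) == T_all)
  ctr <- colMeans(X_raw[, -1, drop = FALSE])
  Xc <- sweep(X_raw[, -1, drop = FALSE], 2, ctr)
  ss <- colSums(Xc^2)
  bad <- ss <= 0 | !is.finite(ss)
  if (any(bad)) {
    warning(sum(bad), " zero-variance column(s) dropped: ",
            paste(block$gene[bad], collapse = ", "))
    Xc <- Xc[, !bad, drop = FALSE]
    ctr <- ctr[!bad]; ss <- ss[!bad]
    block <- block[!bad, , drop = FALSE]
    if (nrow(block) == 0) stop("no informative gene column remains")
    # re-index pathways that may have emptied
    kept <- sort(unique(block$k))
    block$k <- match(block$k, kept)
    if (!is.null(pathways)) pathways <- pathways[kept]
    X_raw <- X_raw[, c(TRUE, !bad), drop = FALSE]
  }
  scl <- sqrt(ss / N)
  X <- cbind(1, sweep(Xc, 2, scl, "/"))
  dimnames(X) <- dimnames(X_raw)
  K <- max(block$k)
  Tk <- as.integer(table(factor(block$k, levels = seq_len(K))))
  if (is.null(pathways)) pathways <- unique(block$pathway)
  structure(list(X = X, X_raw = X_raw, block = block, N = N, K = K,
                 Tk = Tk, pathways = pathways, center = ctr, scale = scl),
            class = "pharaoh_design")
}

# apply training-fold standardization statistics to held-out raw columns
apply_standardization <- function(X_raw, center, scale) {
  Xc <- sweep(X_raw[, -1, drop = FALSE], 2, center)
  cbind(1, sweep(Xc, 2, scale, "/"))
}

#' @exportS3Method base::print
print.pharaoh_design <- function(x, ...) {
  cat("pharaoh_design:", x$N, "samples,", x$K, "pathways,",
      nrow(x$block), "gene columns\n")
  cat("  genes per pathway:", paste(x$Tk, collapse = ", "), "\n")
  invisible(x)
}
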