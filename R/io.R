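#' Read a GMT gene-set file
#'
#' Each line: pathway id, description, then one or more gene ids,
#' tab-separated. Pathway order in the file is preserved.
#'
#' @param path path to the GMT file.
#' @return named list mapping pathway id to a character vector of genes;
#'   descriptions kept in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(), description = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], " in ", path,
         ": expected at least 3 tab-separated fields")
  ids <- vapply(fields, `[[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate pathway id in GMT: ", dup[1])
  out <- lapply(fields, function(f) f[-(1:2)])
  names(out) <- ids
  attr(out, "description") <- vapply(fields, `[[`, character(1), 2)
  out
}

#' Write a GMT gene-set file
#'
#' @param pathways named list mapping pathway id to gene ids.
#' @param path output path.
#' @param description optional vector of descriptions (default `"na"`).
#' @export
write_gmt <- function(pathways, path, description = NULL) {
  if (is.null(description)) description <- rep("na", length(pathways))
  lines <- vapply(seq_along(pathways), function(i)
    paste(c(names(pathways)[i], description[i], pathways[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a headered TSV dosage matrix (samples x variants)
#'
#' First column holds sample ids; remaining columns hold allele counts.
#'
#' @param path path to the TSV file.
#' @param maf optional known minor allele frequencies (else estimated).
#' @return a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path, maf = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("dosage TSV needs a sample column plus variants")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  genotype_matrix(m, sample_ids = as.character(df[[1]]),
                  variant_ids = colnames(df)[-1], maf = maf)
}

#' Write a dosage matrix as headered TSV
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(sample = genotypes$sample_ids,
                   genotypes$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a variant-to-gene map
#'
#' Two tab-separated columns: variant id, gene id. A header line is
#' detected (and skipped) if its first field is `variant`.
#'
#' @param path path to the TSV file.
#' @return named character vector mapping variant id to gene id.
#' @export
read_variant_gene_map <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  header <- identical(tolower(first[1]), "variant")
  df <- utils::read.delim(path, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("variant-gene map needs two tab-separated columns")
  v2g <- as.character(df[[2]])
  names(v2g) <- as.character(df[[1]])
  v2g
}

#' Read genotype dosages from a VCF
#'
#' Extracts per-sample alternate allele counts from the GT field (phased
#' or unphased diploid calls; missing calls become NA). MAF is estimated
#' from the observed dosages and folded onto (0, 0.5].
#'
#' @param path path to a VCF (optionally gzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf_dosages <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(x) {
    alleles <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == "." | a == ""))
        return(NA_real_)
      sum(a != "0")
    }, numeric(1))
  }
  dos <- t(apply(gt, 1, count_alt))
  dimnames(dos) <- dimnames(gt)
  ids <- rownames(dos)
  if (is.null(ids) || anyNA(ids))
    ids <- paste(vcfR::getCHROM(vcf), vcfR::getPOS(vcf), sep = ":")
  genotype_matrix(t(dos), sample_ids = colnames(gt), variant_ids = ids)
}

#' Read a clustered phenotype table
#'
#' Headered TSV with the sample id in the first column and Q phenotype
#' columns. If `sample_ids` is given, rows are reordered to match and
#' restricted to the overlap (complete cases only); zero overlap is an
#' error.
#'
#' @param path path to the TSV file.
#' @param sample_ids optional genotype sample order to align to.
#' @return list with `Y` (N x Q numeric matrix), `samples`,
#'   `family_suggested` (`"binomial"` if every column is \{0,1\}-valued,
#'   else `"gaussian"`).
#' @export
read_phenotypes <- function(path, sample_ids = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype TSV needs a sample column plus phenotypes")
  samples <- as.character(df[[1]])
  Y <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(Y) <- "double"
  rownames(Y) <- samples
  if (!is.null(sample_ids)) {
    common <- intersect(sample_ids, samples)
    if (length(common) == 0)
      stop("no overlapping samples between genotypes and phenotypes")
    if (length(common) < length(sample_ids))
      message(length(common), " of ", length(sample_ids),
              " genotyped samples have phenotypes")
    Y <- Y[common, , drop = FALSE]  # intersect() keeps genotype order
    samples <- common
  }
  keep <- stats::complete.cases(Y)
  if (!all(keep)) {
    message(sum(!keep), " samples with incomplete phenotypes removed")
    Y <- Y[keep, , drop = FALSE]
    samples <- samples[keep]
  }
  binary <- all(Y %in% c(0, 1))
  list(Y = Y, samples = samples,
       family_suggested = if (binary) "binomial" else "gaussian")
}

#' Write phenotypes as headered TSV
#'
#' @param Y N x Q phenotype matrix with sample rownames (or supply
#'   `samples`).
#' @param path output path.
#' @param samples optional sample ids.
#' @export
write_phenotypes <- function(Y, path, samples = NULL) {
  samples <- samples %||% rownames(Y) %||% paste0("S", seq_len(nrow(Y)))
  df <- data.frame(sample = samples, Y, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the fit and test reports of a pipeline run
#'
#' @param test a `pharaoh_perm_test` object.
#' @param dir output directory (created if needed).
#' @param digits significant digits for p/q columns (default 6).
#' @return character vector of written paths.
#' @export
write_test_report <- function(test, dir, digits = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) signif(x, digits)
  pw <- test$pathways
  pw$T <- fmt(pw$T); pw$p <- fmt(pw$p); pw$q <- fmt(pw$q)
  pw$wy_p <- fmt(pw$wy_p)
  f1 <- file.path(dir, "pathway_tests.tsv")
  utils::write.table(pw, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  gn <- test$genes
  gn$p <- fmt(gn$p); gn$q <- fmt(gn$q)
  f2 <- file.path(dir, "gene_tests.tsv")
  utils::write.table(gn, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  c(f1, f2)
}

#' Run the full pipeline from a configuration
#'
#' Stages: read inputs, collapse to the standardized design, optionally
#' cross-validate the penalties, fit, permutation-test, write reports and
#' a manifest (seeds, penalties, package version). Errors are re-raised
#' with the failing stage named.
#'
#' @param config a named list or a path to a YAML file with entries:
#'   `genotypes` (dosage TSV or VCF path), `variant_gene_map`, `gmt`,
#'   `phenotypes`, `output_dir`; optional `family`, `corstr`,
#'   `maf_threshold`, `lambda_G`, `lambda_P`, `cv` (logical),
#'   `cv_grid` (numeric vector), `k_folds`, `n_perm`, `seed`.
#' @return (invisibly) list with `design`, `cv` (or NULL), `test`, and the
#'   written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("genotypes", "variant_gene_map", "gmt", "phenotypes",
            "output_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing: ", paste(miss, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  for (p in c("genotypes", "variant_gene_map", "gmt", "phenotypes"))
    if (!file.exists(config[[p]]))
      stop("[input] file not found: ", config[[p]], call. = FALSE)

  geno <- stage("read-genotypes", {
    if (grepl("\\.vcf(\\.gz)?$", config$genotypes))
      read_vcf_dosages(config$genotypes)
    else read_dosage_tsv(config$genotypes)
  })
  annot <- stage("read-annotation", {
    v2g <- read_variant_gene_map(config$variant_gene_map)
    pathway_annotation(v2g, read_gmt(config$gmt))
  })
  phen <- stage("read-phenotypes",
                read_phenotypes(config$phenotypes, geno$sample_ids))
  keep <- match(phen$samples, geno$sample_ids)
  geno$dosages <- geno$dosages[keep, , drop = FALSE]
  geno$sample_ids <- phen$samples
  family <- config$family %||% phen$family_suggested
  if (family == "binomial" && !all(phen$Y %in% c(0, 1)))
    stop("[read-phenotypes] continuous phenotype column with ",
         "family = binomial", call. = FALSE)

  design <- stage("collapse",
                  build_design(geno, annot,
                               maf_threshold = config$maf_threshold %||% 0.05))
  seed <- config$seed %||% 1L
  corstr <- config$corstr %||% "exchangeable"
  cv <- NULL
  if (isTRUE(config$cv)) {
    grid <- config$cv_grid %||% c(0.01, 0.1, 1, 10, 100)
    cv <- stage("cv", pharaoh_cv(design, phen$Y,
                                 lambda_G_values = grid,
                                 lambda_P_values = grid,
                                 k_folds = config$k_folds %||% 5,
                                 fold_seed = seed, family = family,
                                 corstr = corstr))
    lambda_G <- cv$lambda_G; lambda_P <- cv$lambda_P
  } else {
    lambda_G <- config$lambda_G %||% 1
    lambda_P <- config$lambda_P %||% 1
  }
  test <- stage("test",
                pharaoh_perm_test(design, phen$Y, lambda_G = lambda_G,
                                  lambda_P = lambda_P, family = family,
                                  corstr = corstr,
                                  n_perm = config$n_perm %||% 1000,
                                  seed = seed, force = TRUE))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- stage("write", {
    out <- write_test_report(test, config$output_dir)
    if (!is.null(cv)) {
      fcv <- file.path(config$output_dir, "cv_table.tsv")
      utils::write.table(cv$cv_table, fcv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out <- c(out, fcv)
    }
    manifest <- list(seed = seed, lambda_G = lambda_G,
                     lambda_P = lambda_P, family = family,
                     corstr = corstr,
                     n_perm = config$n_perm %||% 1000,
                     n_samples = design$N, n_pathways = design$K,
                     package_version =
                       as.character(utils::packageVersion("pharaohgee")))
    fman <- file.path(config$output_dir, "manifest.json")
    jsonlite::write_json(manifest, fman, auto_unbox = TRUE, pretty = TRUE)
    c(out, fman)
  })
  invisible(list(design = design, cv = cv, test = test, files = files))
}
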