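#' Simulate RNA-seq counts with cis-eQTL effects
#'
#' Negative-binomial counts per gene and sample, with varying library
#' sizes and optional dosage-dependent cis-eQTL effects on the log-mean
#' of designated genes.
#'
#' @param geno a `genotype_matrix`; eQTL effects act on its dosages.
#' @param n_genes number of genes.
#' @param eqtl `NULL`, or a data.frame with columns `gene` (index),
#'   `variant` (index into `geno`), `log2fc` (log2 fold change per
#'   dosage copy).
#' @param seed integer seed.
#' @param mean_log_expr,sd_log_expr distribution of baseline gene means
#'   (natural log of expected counts at the reference library size).
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param lib_size_cv coefficient of variation of library size factors.
#' @return list of class `"expression_matrix"`: `counts` (genes x
#'   samples integer matrix, gene ids in rownames), `lib_size`,
#'   `eqtl` (the spec used).
#' @export
simulate_expression <- function(geno, n_genes, eqtl = NULL, seed = 1,
                                mean_log_expr = 4, sd_log_expr = 1.5,
                                dispersion = 0.1, lib_size_cv = 0.3) {
  if (n_genes <= 0) stop("n_genes must be positive")
  dosage <- geno$dosage
  n <- nrow(dosage)
  set.seed(seed)
  base <- stats::rnorm(n_genes, mean_log_expr, sd_log_expr)
  sf <- exp(stats::rnorm(n, 0, lib_size_cv))
  logmu <- outer(base, log(sf), `+`)
  if (!is.null(eqtl)) {
    stopifnot(all(c("gene", "variant", "log2fc") %in% names(eqtl)))
    for (k in seq_len(nrow(eqtl))) {
      g <- eqtl$gene[k]
      logmu[g, ] <- logmu[g, ] +
        log(2) * eqtl$log2fc[k] * dosage[, eqtl$variant[k]]
    }
  }
  counts <- matrix(
    stats::rnbinom(n_genes * n, mu = exp(logmu), size = 1 / dispersion),
    n_genes, n
  )
  rownames(counts) <- sprintf("gene%05d", seq_len(n_genes))
  colnames(counts) <- rownames(dosage)
  structure(list(counts = counts, lib_size = colSums(counts), eqtl = eqtl),
            class = "expression_matrix")
}

#' Filter lowly expressed genes on counts per million
#'
#' Drops a gene iff the fraction of samples in which its CPM falls below
#' `min_cpm` is at least `max_fraction_low` (the boundary is inclusive:
#' a gene low in exactly that fraction of samples is dropped).
#'
#' @param counts genes x samples nonnegative count matrix.
#' @param min_cpm CPM threshold (default 4).
#' @param max_fraction_low fraction of low samples at which a gene is
#'   excluded (default 0.985).
#' @return integer index of retained genes.
#' @export
cpm_filter <- function(counts, min_cpm = 4, max_fraction_low = 0.985) {
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    bad <- colnames(counts)[lib <= 0]
    if (is.null(bad)) bad <- which(lib <= 0)
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  cpm <- edgeR::cpm(counts)
  frac_low <- rowMeans(cpm < min_cpm)
  which(frac_low < max_fraction_low)
}

#' Residualize log-expression on technical and biological covariates
#'
#' Per-gene ordinary least-squares residuals of `log2(CPM + 0.5)` (or any
#' supplied expression matrix) on the covariate design. Residuals are
#' orthogonal to every covariate column.
#'
#' @param expr genes x samples matrix of expression values (already
#'   log-scale), or counts with `from_counts = TRUE` to apply
#'   `log2(CPM + 0.5)` first.
#' @param covariates data.frame or matrix of per-sample covariates
#'   (factors are expanded); an intercept is always included. `NULL`
#'   residualizes on the intercept alone (per-gene centering).
#' @param from_counts transform counts to log2(CPM + 0.5) first.
#' @return genes x samples residual matrix.
#' @export
residualize_expression <- function(expr, covariates = NULL,
                                   from_counts = FALSE) {
  if (from_counts) expr <- log2(edgeR::cpm(expr) + 0.5)
  X <- if (is.null(covariates)) {
    matrix(1, ncol(expr), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    build_design(covariates)
  }
  if (nrow(X) != ncol(expr)) stop("covariate rows must match samples")
  if (anyNA(X)) stop("missing covariate values")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  res <- t(qr.resid(qr_x, t(expr)))
  dimnames(res) <- dimnames(expr)
  res
}

# Expand a covariate table to a numeric design matrix with intercept.
build_design <- function(covariates) {
  if (is.matrix(covariates)) {
    X <- cbind(`(Intercept)` = 1, covariates)
    return(X)
  }
  df <- as.data.frame(covariates)
  stats::model.matrix(~ ., data = df)
}
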