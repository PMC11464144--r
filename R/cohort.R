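#' Specification of genetic and residual trait structure
#'
#' Defines how the three analysis traits (eGFRcr, eGFRcys, sRAGE) are
#' generated: per-variant effects, residual correlation, heritability and
#' the fraction of samples shared across scans.
#'
#' `C` is given on the analysis-trait scale: the default reproduces the
#' cohort-level structure this package emulates, +0.70 between the two
#' eGFR measures and -0.25 / -0.30 between each eGFR and sRAGE.
#'
#' @param beta m x 3 matrix of per-variant effects in units of latent
#'   trait SD (columns: eGFRcr, eGFRcys, sRAGE), or `NULL` for no variant
#'   effects. Sparse specification: a data.frame with columns
#'   `variant` (index), `trait` (1:3 or name), `beta` is also accepted.
#' @param C 3 x 3 residual correlation matrix, unit diagonal, positive
#'   definite.
#' @param h2 per-trait polygenic heritability in `[0, 1)`; recycled to 3.
#' @param overlap fraction of samples shared across the three scans in
#'   `[0, 1]` (1 = fully overlapping, the design of the emulated study).
#' @return list of class `"effect_spec"`.
#' @export
effect_spec <- function(beta = NULL,
                        C = default_trait_correlation(),
                        h2 = 0.3, overlap = 1) {
  C <- as.matrix(C)
  stopifnot(nrow(C) == 3, ncol(C) == 3)
  if (max(abs(C - t(C))) > 1e-8 || any(abs(diag(C) - 1) > 1e-8)) {
    stop("C must be symmetric with unit diagonal")
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("C must be positive definite")
  h2 <- rep_len(h2, 3)
  if (any(h2 < 0) || any(h2 >= 1)) stop("h2 must lie in [0, 1)")
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  structure(list(beta = beta, C = C, h2 = h2, overlap = overlap),
            class = "effect_spec")
}

#' Default residual correlation among eGFRcr, eGFRcys and sRAGE
#' @return 3 x 3 correlation matrix.
#' @export
default_trait_correlation <- function() {
  C <- diag(3)
  dimnames(C) <- list(c("egfr_cr", "egfr_cys", "srage"),
                      c("egfr_cr", "egfr_cys", "srage"))
  C[1, 2] <- C[2, 1] <- 0.70
  C[1, 3] <- C[3, 1] <- -0.25
  C[2, 3] <- C[3, 2] <- -0.30
  C
}

# Concentration-scale location/scale defaults (natural-log scale), matched
# to typical cohort magnitudes: creatinine ~1.05 mg/dL, cystatin C
# ~1.08 mg/L, sRAGE ~601.8 pg/mL, with lognormal CVs of roughly 0.3, 0.38
# and 0.7 respectively.
default_trait_scales <- function() {
  list(
    meanlog = c(scr = log(1.05), scys = log(1.08), srage = log(601.8)),
    sdlog   = c(scr = 0.28, scys = 0.33, srage = 0.62)
  )
}

# Covariate effects on the concentration (natural-log) scale, per trait
# (scr, scys, srage). Magnitudes are configuration defaults, not estimates.
default_covariate_effects <- function() {
  list(
    age  = c(0.004, 0.008, 0.004),      # per year
    age2 = c(0, 0, 0),                  # per year^2 (centered at 70)
    female = c(-0.12, -0.03, 0.05),
    center = c(0.02, 0.02, 0.05),       # per unit of center contrast
    pc1  = c(0.02, 0.02, 0.02)
  )
}

#' Simulate correlated phenotypes on a genotyped pedigree
#'
#' Latent standardized traits (eGFRcr-, eGFRcys- and sRAGE-directed) are
#' the sum of additive variant effects, a polygenic term with covariance
#' `h2 * 2K` per trait (sharing the cross-trait correlation `C`), and
#' residuals with correlation `C` scaled to `1 - h2`. The latent traits
#' are mapped to serum concentrations (creatinine mg/dL, cystatin C mg/L,
#' sRAGE pg/mL) on the natural-log scale — the eGFR-directed latents with
#' a sign flip, since eGFR falls as its marker concentration rises — and
#' covariate effects (age, age squared, sex, field center, PC1) are added
#' on that scale.
#'
#' @param geno a `genotype_matrix` from [simulate_genotypes()].
#' @param kinship kinship matrix \eqn{\phi} from [build_kinship()], rows
#'   aligned with `geno$dosage`.
#' @param spec an [effect_spec()].
#' @param seed integer seed.
#' @param scales concentration scales, see `default_trait_scales()`.
#' @param cov_effects covariate effect sizes, see
#'   `default_covariate_effects()`.
#' @return list with
#'   `phenotypes`: data.frame (`id`, `scr`, `scys`, `srage`, `age`,
#'     `sex`, `center`, `pc1`);
#'   `latent`: n x 3 matrix of true latent trait values (analysis scale,
#'     before covariates and concentration scaling);
#'   `spec`: the effect spec used.
#' @export
simulate_phenotypes <- function(geno, kinship, spec = effect_spec(),
                                seed = 1,
                                scales = default_trait_scales(),
                                cov_effects = default_covariate_effects()) {
  stopifnot(inherits(spec, "effect_spec"))
  dosage <- geno$dosage
  n <- nrow(dosage)
  stopifnot(nrow(kinship) == n)
  set.seed(seed)

  C <- spec$C
  h2 <- spec$h2
  Lc <- t(chol(C))

  # polygenic component: columns have covariance 2K, rows correlation C
  G2 <- 2 * kinship
  ev <- eigen(G2, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  Lk <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  A <- Lk %*% matrix(stats::rnorm(n * 3), n, 3) %*% t(Lc)
  A <- sweep(A, 2, sqrt(h2), `*`)

  E <- matrix(stats::rnorm(n * 3), n, 3) %*% t(Lc)
  E <- sweep(E, 2, sqrt(1 - h2), `*`)

  latent <- A + E
  if (!is.null(spec$beta)) {
    B <- expand_beta(spec$beta, ncol(dosage))
    idxv <- which(rowSums(B != 0) > 0)
    if (length(idxv)) {
      Dc <- scale(dosage[, idxv, drop = FALSE], center = TRUE, scale = FALSE)
      latent <- latent + Dc %*% B[idxv, , drop = FALSE]
    }
  }
  colnames(latent) <- c("egfr_cr", "egfr_cys", "srage")

  age <- pmin(pmax(stats::rnorm(n, 70, 15), 24), 110)
  sex <- ifelse(stats::runif(n) < 0.55, "female", "male")
  center <- sample(paste0("C", 1:4), n, replace = TRUE)
  pc1 <- stats::rnorm(n)

  # concentration scale: eGFR-directed latents flip sign
  conc_latent <- latent %*% diag(c(-1, -1, 1))
  agec <- age - 70
  centern <- as.integer(factor(center)) - mean(as.integer(factor(center)))
  covmat <- cbind(agec, agec^2, sex == "female", centern, pc1)
  eff <- rbind(cov_effects$age, cov_effects$age2, cov_effects$female,
               cov_effects$center, cov_effects$pc1)
  loge <- sweep(sweep(conc_latent, 2, scales$sdlog, `*`), 2,
                scales$meanlog, `+`) + covmat %*% eff

  phen <- data.frame(
    id = rownames(dosage),
    scr = exp(loge[, 1]), scys = exp(loge[, 2]), srage = exp(loge[, 3]),
    age = age, sex = sex, center = center, pc1 = pc1,
    stringsAsFactors = FALSE
  )
  list(phenotypes = phen, latent = latent, spec = spec)
}

expand_beta <- function(beta, m) {
  if (is.matrix(beta)) {
    stopifnot(nrow(beta) == m, ncol(beta) == 3)
    return(beta)
  }
  stopifnot(is.data.frame(beta),
            all(c("variant", "trait", "beta") %in% names(beta)))
  B <- matrix(0, m, 3)
  tr <- beta$trait
  if (is.character(tr)) {
    tr <- match(tr, c("egfr_cr", "egfr_cys", "srage"))
  }
  B[cbind(as.integer(beta$variant), as.integer(tr))] <- beta$beta
  B
}

#' Derived analysis traits from a phenotype table
#'
#' Applies the CKD-EPI equations and returns the analysis traits
#' (eGFRcr, eGFRcys, sRAGE) alongside CKD flags.
#'
#' @param phen phenotype data.frame from [simulate_phenotypes()].
#' @return data.frame with `id`, `egfr_cr`, `egfr_cys`, `srage`,
#'   `ckd_cr`, `ckd_cys`.
#' @export
derive_traits <- function(phen) {
  ecr <- egfr_creatinine(phen$scr, phen$age, phen$sex)
  ecys <- egfr_cystatin(phen$scys, phen$age, phen$sex)
  data.frame(id = phen$id, egfr_cr = ecr, egfr_cys = ecys,
             srage = phen$srage,
             ckd_cr = ckd_flag(ecr), ckd_cys = ckd_flag(ecys),
             stringsAsFactors = FALSE)
}

#' Simulate a complete family cohort
#'
#' Convenience wrapper: pedigree, kinship, genotypes, phenotypes and
#' (optionally) expression counts, under one master seed.
#'
#' @param n_fam,n_children,n_grandchildren pedigree layout, see
#'   [simulate_pedigree()].
#' @param m number of variants.
#' @param maf MAF spectrum (value, vector or function).
#' @param spec an [effect_spec()].
#' @param n_genes number of expression genes (0 to skip).
#' @param eqtl optional eQTL specification, see [simulate_expression()].
#' @param seed master seed; sub-seeds are derived deterministically.
#' @return list with `ped`, `kinship`, `geno`, `phen` (see
#'   [simulate_phenotypes()]), `traits`, and optionally `expr`.
#' @export
simulate_cohort <- function(n_fam = 50, n_children = 3, n_grandchildren = 2,
                            m = 2000, maf = maf_spectrum(),
                            spec = effect_spec(), n_genes = 0,
                            eqtl = NULL, seed = 1) {
  ped <- simulate_pedigree(n_fam, n_children, n_grandchildren, seed = seed)
  K <- build_kinship(ped)
  set.seed(seed)
  geno <- simulate_genotypes(ped, m, maf, seed = seed + 1L)
  phen <- simulate_phenotypes(geno, K, spec, seed = seed + 2L)
  out <- list(ped = ped, kinship = K, geno = geno, phen = phen,
              traits = derive_traits(phen$phenotypes))
  if (n_genes > 0) {
    out$expr <- simulate_expression(geno, n_genes, eqtl = eqtl,
                                    seed = seed + 3L)
  }
  out
}
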