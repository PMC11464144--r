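#' Prepare a trait for association scanning
#'
#' Natural-log transforms a strictly positive trait and assembles the
#' fixed-effects design (intercept, age, age squared, sex, field center,
#' PC1). Covariates are carried into the mixed model as fixed effects,
#' not pre-residualized.
#'
#' @param values positive trait values (eGFR or sRAGE scale).
#' @param covariates data.frame with columns `age`, `sex`, `center`,
#'   `pc1` (extra columns are included as supplied); an `age2` column, if
#'   present, must equal `age^2`.
#' @param ids optional individual ids used in error messages.
#' @return list with `y` (log trait) and `X` (design matrix).
#' @export
prepare_trait <- function(values, covariates, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(values))
  if (anyNA(values) || any(values <= 0)) {
    bad <- ids[which(is.na(values) | values <= 0)]
    stop("nonpositive or missing trait value for individual(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  cov <- as.data.frame(covariates)
  if (anyNA(cov)) {
    badr <- which(rowSums(is.na(cov)) > 0)
    stop("missing covariate cell for individual(s): ",
         paste(utils::head(ids[badr], 5), collapse = ", "))
  }
  if ("age2" %in% names(cov)) {
    if (max(abs(cov$age2 - cov$age^2)) > 1e-6) {
      stop("age2 column inconsistent with age^2")
    }
  } else if ("age" %in% names(cov)) {
    cov$age2 <- cov$age^2
  }
  X <- stats::model.matrix(~ ., data = cov)
  list(y = log(values), X = X)
}

#' REML fit of a kinship linear mixed model
#'
#' Fits \eqn{y = X\beta + g + e}, \eqn{g \sim N(0, \sigma^2_g \cdot 2K)},
#' \eqn{e \sim N(0, \sigma^2_e I)} by restricted maximum likelihood.
#' The numerator relationship matrix \eqn{2K} is eigendecomposed once;
#' the REML criterion is profiled to a one-dimensional optimization over
#' \eqn{\log\delta}, \eqn{\delta = \sigma^2_e/\sigma^2_g}.
#'
#' @param y response vector (log trait).
#' @param X fixed-effects design (with intercept).
#' @param K kinship matrix \eqn{\phi}; the model uses \eqn{2K}. Eigenvalues
#'   of \eqn{2K} in `[-1e-8, 0)` are clipped to 0; more negative values
#'   are an error.
#' @param relatedness multiplier applied to `K` (default 2, the numerator
#'   relationship convention).
#' @return list of class `"lmm_fit"`: variance components `sigma2_g`,
#'   `sigma2_e`, ratio `delta`, `h2 = sigma2_g / (sigma2_g + sigma2_e)`,
#'   fixed effects `beta` with `se`, REML log-likelihood `loglik`, and the
#'   rotation (`U`, `lambda`) for downstream association.
#' @export
lmm_reml_fit <- function(y, X, K, relatedness = 2) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  G <- relatedness * K
  ev <- eigen(G, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) < -1e-8 * max(1, max(lam))) {
    stop("kinship matrix is not positive semidefinite (min eigenvalue ",
         format(min(lam)), ")")
  }
  lam <- pmax(lam, 0)
  U <- ev$vectors
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)
  p <- ncol(X)

  reml <- function(logdelta) {
    d <- exp(logdelta)
    w <- 1 / (lam + d)
    XtWX <- crossprod(Xr, w * Xr)
    cXtWX <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(cXtWX)) return(-1e300)
    beta <- backsolve(cXtWX, forwardsolve(t(cXtWX), crossprod(Xr, w * yr)))
    r <- yr - Xr %*% beta
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(lam + d)) +
              2 * sum(log(diag(cXtWX))) + (n - p))
  }
  # coarse grid then local refinement: deterministic and robust to the
  # flat profile when sigma2_g ~ 0
  grid <- seq(-12, 12, length.out = 49)
  vals <- vapply(grid, reml, numeric(1))
  i0 <- which.max(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  w <- 1 / (lam + delta)
  XtWX <- crossprod(Xr, w * Xr)
  XtWXi <- solve(XtWX)
  beta <- drop(XtWXi %*% crossprod(Xr, w * yr))
  r <- yr - Xr %*% beta
  sigma2_g <- sum(w * r^2) / (n - p)
  sigma2_e <- delta * sigma2_g
  se <- sqrt(sigma2_g * diag(XtWXi))
  names(beta) <- names(se) <- colnames(X)
  structure(list(
    sigma2_g = sigma2_g, sigma2_e = sigma2_e, delta = delta,
    h2 = sigma2_g / (sigma2_g + sigma2_e),
    beta = beta, se = se, loglik = opt$objective,
    U = U, lambda = lam, y = y, X = X
  ), class = "lmm_fit")
}

#' Single-variant association under a fitted mixed model
#'
#' Per-variant Wald tests of the additive dosage effect with the variance
#' components fixed at the null-model REML fit (the standard two-step
#' approximation: fit variance once, then generalized least squares per
#' variant). Two-sided p-values use the normal reference.
#'
#' @param fit an `"lmm_fit"` from [lmm_reml_fit()].
#' @param geno a `genotype_matrix`, or a dosage matrix (with `map`
#'   supplied separately).
#' @param map variant map (required when `geno` is a bare matrix).
#' @param scan_id trait/scan label stored on the result.
#' @return A `scan_table` data.frame: `snp`, `chr`, `pos`, `ea`, `oa`,
#'   `beta`, `se`, `p`, `mac`, `maf`, `n`. Variants with constant dosage
#'   are skipped with a message.
#' @export
lmm_association <- function(fit, geno, map = NULL, scan_id = "trait") {
  if (inherits(geno, "genotype_matrix")) {
    dosage <- geno$dosage
    if (is.null(map)) map <- geno$map
  } else {
    dosage <- geno
  }
  if (is.null(map)) {
    map <- data.frame(snp = colnames(dosage),
                      chr = 1L, pos = seq_len(ncol(dosage)),
                      ea = "A", oa = "G", stringsAsFactors = FALSE)
  }
  n <- length(fit$y)
  stopifnot(nrow(dosage) == n)
  w <- 1 / (fit$lambda + fit$delta)
  sw <- sqrt(w)
  yw <- sw * crossprod(fit$U, fit$y)
  Xw <- sw * crossprod(fit$U, fit$X)
  qx <- qr(Xw)
  ry <- qr.resid(qx, yw)
  p_fixed <- ncol(fit$X)

  const <- apply(dosage, 2, function(g) max(g) == min(g))
  if (any(const)) {
    message("skipping ", sum(const), " constant-dosage variant(s)")
  }
  keep <- which(!const)
  Gw <- sw * crossprod(fit$U, dosage[, keep, drop = FALSE])
  Rg <- qr.resid(qx, Gw)
  ssg <- colSums(Rg^2)
  bnum <- colSums(Rg * drop(ry))
  beta <- bnum / ssg
  rss <- sum(ry^2) - beta^2 * ssg
  s2 <- rss / (n - p_fixed - 1)
  se <- sqrt(s2 / ssg)
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))

  mac <- minor_allele_count(dosage[, keep, drop = FALSE])
  out <- data.frame(
    snp = map$snp[keep], chr = map$chr[keep], pos = map$pos[keep],
    ea = map$ea[keep], oa = map$oa[keep],
    beta = beta, se = se, p = pv,
    mac = mac, maf = mac / (2 * n), n = n,
    stringsAsFactors = FALSE
  )
  scan_table(out, scan_id = scan_id)
}

#' Full per-trait genome scan
#'
#' Convenience driver: log-transform and design construction
#' ([prepare_trait()]), MAC and allele filtering ([mac_filter()]), null
#' REML fit ([lmm_reml_fit()]) and per-variant association
#' ([lmm_association()]).
#'
#' @param values positive trait values.
#' @param covariates covariate data.frame, see [prepare_trait()].
#' @param geno a `genotype_matrix`.
#' @param K kinship matrix.
#' @param scan_id trait label.
#' @param mac_threshold minimum retained minor allele count.
#' @return a `scan_table` with attribute `lambda_gc` and `fit`.
#' @export
gwas_scan <- function(values, covariates, geno, K, scan_id = "trait",
                      mac_threshold = 20) {
  pt <- prepare_trait(values, covariates,
                      ids = rownames(geno$dosage))
  keep <- mac_filter(geno$dosage, mac_threshold,
                     ea = geno$map$ea, oa = geno$map$oa)
  sub <- list(dosage = geno$dosage[, keep, drop = FALSE],
              map = geno$map[keep, , drop = FALSE])
  class(sub) <- "genotype_matrix"
  fit <- lmm_reml_fit(pt$y, pt$X, K)
  tab <- lmm_association(fit, sub, scan_id = scan_id)
  attr(tab, "lambda_gc") <- genomic_lambda(tab$p)
  attr(tab, "fit") <- fit[c("sigma2_g", "sigma2_e", "delta", "h2")]
  tab
}

#' Genomic-control inflation factor
#'
#' \eqn{\lambda = \mathrm{median}(\chi^2_1\text{-quantiles of } 1-p) /
#' 0.4549364}, the null median of a 1-df chi-square.
#'
#' @param p vector of p-values in (0, 1].
#' @return scalar lambda.
#' @export
genomic_lambda <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}
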