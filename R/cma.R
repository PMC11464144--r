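#' Cross-classify two scans' p-values at a significance cut
#'
#' Markers with p below `trim` in either scan are removed first, so that
#' the correlation estimate reflects the null bulk rather than shared
#' signals; the remainder are cross-classified by `I(p < cut)` in each
#' scan.
#'
#' @param p1,p2 aligned p-value vectors (same markers), or two
#'   `scan_table`s (aligned on `snp`).
#' @param cut dichotomization point (default 0.5, the null median).
#' @param trim signal-exclusion threshold (default 1e-4); `trim = 0`
#'   keeps all markers.
#' @return list with counts `a` (both below cut), `b` (scan 1 only),
#'   `c` (scan 2 only), `d` (neither), and `n_used`.
#' @export
dichotomize_scans <- function(p1, p2, cut = 0.5, trim = 1e-4) {
  if (inherits(p1, "data.frame") && inherits(p2, "data.frame")) {
    shared <- intersect(p1$snp, p2$snp)
    if (length(shared) == 0) stop("no shared markers between scans")
    p2 <- p2$p[match(shared, p2$snp)]
    p1 <- p1$p[match(shared, p1$snp)]
  }
  if (length(p1) != length(p2) || length(p1) == 0) {
    stop("no shared markers between scans")
  }
  keep <- p1 >= trim & p2 >= trim
  p1 <- p1[keep]; p2 <- p2[keep]
  s1 <- p1 < cut; s2 <- p2 < cut
  list(a = sum(s1 & s2), b = sum(s1 & !s2), c = sum(!s1 & s2),
       d = sum(!s1 & !s2), n_used = length(p1))
}

#' Maximum-likelihood tetrachoric correlation
#'
#' The correlation of a latent bivariate normal inferred from a 2x2 table
#' of dichotomized indicators. Thresholds are fixed from the margins
#' (`P(Z1 > h) = (a+b)/n`, `P(Z2 > k) = (a+c)/n`) and the correlation is
#' found by root-finding on the upper-orthant probability, which is
#' strictly increasing in rho. A closed-form cosine approximation
#' `cos(pi / (1 + sqrt(ad/bc)))` is available as a fallback.
#'
#' @param a,b,c,d nonnegative 2x2 counts: `a` both positive, `b` first
#'   only, `c` second only, `d` neither.
#' @param estimator `"ml"` (default) or `"cosine"`.
#' @return rho in `[-0.999, 0.999]` (perfect tables are capped).
#' @export
tetrachoric <- function(a, b, c, d, estimator = c("ml", "cosine")) {
  estimator <- match.arg(estimator)
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  n <- a + b + c + d
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("degenerate margins in 2x2 table")
  }
  if (sum(c(a, b, c, d) > 0) < 2) stop("at least two cells must be nonzero")
  if (b == 0 && c == 0) return(0.999)
  if (a == 0 && d == 0) return(-0.999)
  if (estimator == "cosine") {
    if (b == 0 || c == 0) return(0.999)
    if (a == 0 || d == 0) return(-0.999)
    return(cos(pi / (1 + sqrt((a / b) * (d / c)))))
  }
  h <- stats::qnorm((a + b) / n, lower.tail = FALSE)
  k <- stats::qnorm((a + c) / n, lower.tail = FALSE)
  target <- a / n
  f <- function(r) {
    upper_orthant(h, k, r) - target
  }
  lo <- -0.999; hi <- 0.999
  flo <- f(lo); fhi <- f(hi)
  if (flo >= 0) return(-0.999)
  if (fhi <= 0) return(0.999)
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

# P(Z1 > h, Z2 > k) under bivariate normal with correlation r
upper_orthant <- function(h, k, r) {
  mvtnorm::pmvnorm(lower = c(h, k), upper = c(Inf, Inf),
                   corr = matrix(c(1, r, r, 1), 2),
                   algorithm = mvtnorm::GenzBretz(abseps = 1e-10))[1]
}

#' Latent correlation magnitude for two-sided scans
#'
#' Association scans report two-sided p-values, so `I(p < cut)`
#' dichotomizes the *magnitude* of the underlying z-score. This estimator
#' solves the both-tails orthant equation
#' \deqn{P(|Z_1| > c_1, |Z_2| > c_2; \rho) = a/n}
#' for the latent z-score correlation magnitude; the sign of rho is not
#' identifiable from magnitudes (and is not needed by the combiner, whose
#' covariance for two-sided statistics is even in rho).
#'
#' @inheritParams tetrachoric
#' @return |rho| in `[0, 0.999]`.
#' @export
tetrachoric_twosided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  n <- a + b + c + d
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("degenerate margins in 2x2 table")
  }
  if (b == 0 && c == 0) return(0.999)
  c1 <- stats::qnorm(1 - (a + b) / (2 * n))
  c2 <- stats::qnorm(1 - (a + c) / (2 * n))
  target <- a / n
  f <- function(r) {
    2 * (upper_orthant(c1, c2, r) + upper_orthant(c1, c2, -r)) - target
  }
  if (f(0) >= 0) return(0)
  if (f(0.999) <= 0) return(0.999)
  stats::uniroot(f, c(0, 0.999), tol = 1e-9)$root
}

# Covariance of (-2 log p_i, -2 log p_j) for tests with z-score
# correlation rho. "exact": Gauss-Hermite quadrature of the bivariate
# expectation, with a one- or two-sided p-value mapping. "kost": the
# cubic polynomial approximation 3.263 rho + 0.710 rho^2 + 0.027 rho^3
# (one-sided; agrees with the exact quadrature to ~4 decimals).
.gh_cache <- new.env(parent = emptyenv())

#' Covariance of Fisher terms for correlated tests
#'
#' @param rho z-score correlation (scalar).
#' @param two_sided are the combined p-values two-sided? (default TRUE,
#'   the association-scan case).
#' @param method `"exact"` (quadrature) or `"kost"` (one-sided cubic).
#' @param nodes quadrature size.
#' @return covariance of the two chi-square(2) terms.
#' @export
fisher_cov <- function(rho, two_sided = TRUE,
                       method = c("exact", "kost"), nodes = 96) {
  method <- match.arg(method)
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  if (method == "kost") {
    return(3.263 * rho + 0.710 * rho^2 + 0.027 * rho^3)
  }
  if (two_sided && abs(rho) >= 0.9995) return(4)
  if (!two_sided && rho >= 0.9995) return(4)
  key <- as.character(nodes)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- pracma::gaussHermite(nodes)
  }
  e <- .gh_cache[[key]]
  x <- sqrt(2) * e$x
  w <- e$w / sqrt(pi)
  fz <- if (two_sided) {
    function(z) -2 * log(pmax(2 * stats::pnorm(-abs(z)), 1e-300))
  } else {
    function(z) -2 * log(pmax(stats::pnorm(-z), 1e-300))
  }
  s <- sqrt(1 - rho^2)
  f1 <- fz(x)
  zmat <- outer(rho * x, s * x, `+`)
  cond <- fz(zmat) %*% w          # E[f(Z2) | Z1 = x_i]
  ex <- sum(w * f1 * cond)
  mu <- sum(w * f1)
  ex - mu^2
}

#' Between-scan null correlation matrix
#'
#' Pairwise latent correlation of association scans over their shared
#' markers, estimated from median-dichotomized, signal-trimmed p-values.
#' The default estimator is the two-sided orthant MLE
#' ([tetrachoric_twosided()]), matching the two-sided p-values
#' association scans report; `"ml"` (signed single-threshold
#' tetrachoric) and `"cosine"` are available for one-sided inputs.
#'
#' @param scans named list of `scan_table`s (or data.frames with `snp`
#'   and `p`), length >= 2.
#' @param cut,trim see [dichotomize_scans()].
#' @param estimator `"ml-twosided"` (default), `"ml"` or `"cosine"`.
#' @param make_psd project to the nearest positive semidefinite matrix by
#'   eigenvalue clipping if needed (recorded in the result).
#' @return list of class `"scan_correlation"`: `rho` (k x k), `counts`
#'   (per-pair 2x2 lists), `estimator`, `clipped` (logical).
#' @export
scan_correlation <- function(scans, cut = 0.5, trim = 1e-4,
                             estimator = c("ml-twosided", "ml", "cosine"),
                             make_psd = TRUE) {
  estimator <- match.arg(estimator)
  k <- length(scans)
  if (k < 2) stop("need at least 2 scans")
  if (is.null(names(scans))) names(scans) <- paste0("scan", seq_len(k))
  rho <- diag(k)
  dimnames(rho) <- list(names(scans), names(scans))
  counts <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- dichotomize_scans(scans[[i]], scans[[j]], cut = cut, trim = trim)
      r <- switch(estimator,
        "ml-twosided" = tetrachoric_twosided(ct$a, ct$b, ct$c, ct$d),
        "ml" = tetrachoric(ct$a, ct$b, ct$c, ct$d, "ml"),
        "cosine" = tetrachoric(ct$a, ct$b, ct$c, ct$d, "cosine")
      )
      rho[i, j] <- rho[j, i] <- r
      counts[[paste(names(scans)[i], names(scans)[j], sep = ":")]] <- ct
    }
  }
  clipped <- FALSE
  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) < 0) {
    if (!make_psd) stop("scan correlation matrix is not positive semidefinite")
    clipped <- TRUE
    lam <- pmax(ev$values, 1e-8)
    rho <- ev$vectors %*% (lam * t(ev$vectors))
    d <- sqrt(diag(rho))
    rho <- rho / outer(d, d)
    dimnames(rho) <- list(names(scans), names(scans))
  }
  structure(list(rho = rho, counts = counts, estimator = estimator,
                 clipped = clipped),
            class = "scan_correlation")
}

# Quadrature grid for the two-sided / one-sided Fisher-term mapping.
fisher_term <- function(z, two_sided) {
  if (two_sided) -2 * log(pmax(2 * stats::pnorm(-abs(z)), 1e-300))
  else -2 * log(pmax(stats::pnorm(-z), 1e-300))
}

# E[(f1-2)^2 (f2-2)] and E[(f1-2)(f2-2)^2] for a pair of Fisher terms
# with latent z-correlation rho; used for the third-moment match.
fisher_pair_moments <- function(rho, two_sided = TRUE, nodes = 96) {
  if (rho == 0) {
    return(list(cov = 0, g12 = 0, g21 = 0))    # independence, exactly
  }
  if (two_sided && abs(rho) >= 0.9995) {
    return(list(cov = 4, g12 = 16, g21 = 16))  # duplicated scan: chi2_2
  }
  key <- as.character(nodes)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- pracma::gaussHermite(nodes)
  }
  e <- .gh_cache[[key]]
  x <- sqrt(2) * e$x
  w <- e$w / sqrt(pi)
  fx <- fisher_term(x, two_sided)
  s <- sqrt(1 - rho^2)
  zm <- outer(rho * x, s * x, `+`)
  Fm <- fisher_term(zm, two_sided)
  Ef <- Fm %*% w
  Ef2 <- (Fm^2) %*% w
  c1 <- fx - 2
  list(cov = sum(w * fx * Ef) - 4,
       g12 = sum(w * c1^2 * (Ef - 2)),
       g21 = sum(w * c1 * (Ef2 - 4 * Ef + 4)))
}

# E[(f1-2)(f2-2)(f3-2)] under a trivariate normal with the given
# correlations; 3D Gauss-Hermite quadrature.
fisher_triple_moment <- function(r12, r13, r23, two_sided = TRUE,
                                 nodes = 40) {
  if (r12 == 0 && r13 == 0 && r23 == 0) return(0)
  R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
  R[abs(R) >= 0.9995] <- sign(R[abs(R) >= 0.9995]) * 0.9995
  diag(R) <- 1
  L <- t(chol(R))
  key <- as.character(nodes)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- pracma::gaussHermite(nodes)
  }
  e <- .gh_cache[[key]]
  x <- sqrt(2) * e$x
  w <- e$w / sqrt(pi)
  tot <- 0
  for (i in seq_along(x)) {
    c1 <- fisher_term(L[1, 1] * x[i], two_sided) - 2
    c2 <- fisher_term(L[2, 1] * x[i] + L[2, 2] * x, two_sided) - 2
    z3 <- outer(L[3, 2] * x, L[3, 3] * x, `+`) + L[3, 1] * x[i]
    Ec3 <- (fisher_term(z3, two_sided) - 2) %*% w
    tot <- tot + w[i] * c1 * sum(w * c2 * Ec3)
  }
  tot
}

# Null parameters of the Fisher statistic T = sum(-2 log p) for scans
# with latent correlation matrix R: mean, variance, third central
# moment, and the matched shifted-gamma (location a, scale b, shape s).
# With moments = "two" the location is 0 and the gamma is Brown's scaled
# chi-square (b = 2c, s = f/2 in his parametrization).
fisher_null_params <- function(R, two_sided = TRUE,
                               cov_method = c("exact", "kost"),
                               moments = c("three", "two")) {
  cov_method <- match.arg(cov_method)
  moments <- match.arg(moments)
  if (cov_method == "kost") moments <- "two"  # cubic gives cov only
  k <- nrow(R)
  E <- 2 * k
  covsum <- 0
  g_sum <- 0
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (cov_method == "kost") {
          covsum <- covsum + fisher_cov(R[i, j], two_sided, "kost")
        } else {
          pm <- fisher_pair_moments(R[i, j], two_sided)
          covsum <- covsum + pm$cov
          g_sum <- g_sum + pm$g12 + pm$g21
        }
      }
    }
  }
  V <- 4 * k + 2 * covsum
  if (moments == "two") {
    c_scale <- V / (2 * E)
    f <- 2 * E^2 / V
    return(list(E = E, V = V, m3 = NA_real_, a = 0, b = 2 * c_scale,
                s = f / 2, c = c_scale, f = f, moments = moments))
  }
  m3 <- 16 * k + 3 * g_sum
  if (k > 2) {
    for (i in seq_len(k - 2)) {
      for (j in (i + 1):(k - 1)) {
        for (l in (j + 1):k) {
          m3 <- m3 + 6 * fisher_triple_moment(R[i, j], R[i, l], R[j, l],
                                              two_sided)
        }
      }
    }
  }
  if (m3 <= 0) {  # degenerate skewness: fall back to the two-moment fit
    return(fisher_null_params(R, two_sided, cov_method, moments = "two"))
  }
  b <- m3 / (2 * V)
  s <- V / b^2
  a <- E - b * s
  list(E = E, V = V, m3 = m3, a = a, b = b, s = s,
       c = b / 2, f = 2 * s, moments = moments)
}

#' Combine dependent p-values by a moment-matched gamma (Brown's method)
#'
#' Fisher's statistic \eqn{T = \sum_i -2 \ln p_i} has mean \eqn{2k} and,
#' for dependent tests, variance \eqn{4k + 2\sum_{i<j} \mathrm{cov}_{ij}}
#' with the pairwise covariance evaluated from the scans' latent z-score
#' correlation (see [fisher_cov()]). The null is approximated by a gamma
#' family matched on moments. `moments = "two"` is the classical scaled
#' chi-square (`f = 2E^2/Var`, `c = Var/(2E)`, p the upper tail of
#' \eqn{\chi^2_f} at `T/c`). The default `moments = "three"` additionally
#' matches the third central moment with a location-shifted gamma, which
#' repairs the tail of the two-moment fit for two-sided statistics while
#' reducing to it exactly in the symmetric special cases: at `R = I` both
#' give Fisher's \eqn{\chi^2_{2k}}, and at \eqn{\rho = 1} both return the
#' single-scan p-value.
#'
#' @param p vector of k p-values in (0, 1]; p = 0 is rejected.
#' @param R k x k correlation matrix of the scans' statistics.
#' @param two_sided p-values are two-sided (default TRUE).
#' @param cov_method `"exact"` or `"kost"`, see [fisher_cov()]; the
#'   cubic `"kost"` approximation implies `moments = "two"`.
#' @param moments `"three"` (default) or `"two"`.
#' @return list: `T`, `c`, `f` (scaled-chi-square reading of the fitted
#'   gamma: scale and degrees of freedom), `a` (gamma location, 0 for the
#'   two-moment fit), `p` (the combined p-value), `k`.
#' @export
brown_combine <- function(p, R, two_sided = TRUE,
                          cov_method = c("exact", "kost"),
                          moments = c("three", "two")) {
  k <- length(p)
  if (any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  R <- as.matrix(R)
  stopifnot(nrow(R) == k, ncol(R) == k)
  if (max(abs(R)) > 1 + 1e-12) stop("|rho| must be <= 1")
  par <- fisher_null_params(R, two_sided, cov_method, moments)
  T_stat <- sum(-2 * log(p))
  pv <- stats::pgamma(pmax(T_stat - par$a, 0) / par$b, shape = par$s,
                      lower.tail = FALSE)
  list(T = T_stat, c = par$c, f = par$f, a = par$a, p = pv, k = k)
}

#' Combine dependent p-values by a correlated Stouffer statistic
#'
#' \eqn{Z = \sum_i z_i / \sqrt{1^\top R 1}} with
#' \eqn{z_i = \Phi^{-1}(1 - p_i/2) \cdot \mathrm{sign}_i}; the two-sided
#' p-value of Z is returned. Provided as a directional sensitivity
#' combiner alongside [brown_combine()].
#'
#' @param p vector of k p-values in (0, 1].
#' @param signs effect directions (+1/-1).
#' @param R k x k correlation matrix.
#' @return list: `Z`, `p`, `k`.
#' @export
stouffer_combine <- function(p, signs, R) {
  k <- length(p)
  if (any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  stopifnot(length(signs) == k)
  R <- as.matrix(R)
  if (max(abs(R)) > 1 + 1e-12) stop("|rho| must be <= 1")
  z <- stats::qnorm(1 - p / 2) * sign(signs)
  Z <- sum(z) / sqrt(sum(R))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), k = k)
}

#' Correlated meta-analysis across aligned scans
#'
#' For every marker, enumerates each trait subset of size >= 2 whose
#' members all reach the per-scan eligibility cut, combines the subset's
#' p-values with [brown_combine()] under the estimated between-scan
#' correlation, and keeps the subset with the smallest combined p-value
#' as the marker's headline record (ties broken toward the larger subset,
#' then lexicographic trait order). All evaluated subsets are retained in
#' the `subsets` attribute.
#'
#' With `eligibility = NULL`, the full trait set is combined for every
#' marker regardless of per-scan p-values — the form used for genomic
#' control and calibration of the combined scan.
#'
#' @param scans named list of `scan_table`s aligned on `snp`.
#' @param R a `"scan_correlation"` or a plain correlation matrix in scan
#'   order.
#' @param eligibility per-scan p-value cut for a trait to contribute
#'   (default 0.01), or `NULL`.
#' @param two_sided,cov_method,moments passed to [brown_combine()].
#' @return data.frame (class `"cma_table"`): `snp`, `chr`, `pos`,
#'   `subset`, one `p_<scan>` column per scan, `t`, `c`, `f`, `p_cma`.
#'   Attribute `subsets` holds the long (all-subset) table.
#' @export
cma_scan <- function(scans, R, eligibility = 0.01, two_sided = TRUE,
                     cov_method = c("exact", "kost"),
                     moments = c("three", "two")) {
  cov_method <- match.arg(cov_method)
  moments <- match.arg(moments)
  if (inherits(R, "scan_correlation")) R <- R$rho
  k <- length(scans)
  stopifnot(k >= 2, nrow(R) == k)
  if (is.null(names(scans))) names(scans) <- paste0("scan", seq_len(k))
  trait_names <- names(scans)

  all_snp <- unique(unlist(lapply(scans, function(s) s$snp)))
  P <- matrix(NA_real_, length(all_snp), k,
              dimnames = list(all_snp, trait_names))
  for (i in seq_len(k)) {
    P[match(scans[[i]]$snp, all_snp), i] <- scans[[i]]$p
  }
  ref <- scans[[1]]
  chr <- rep(NA, length(all_snp)); pos <- rep(NA_real_, length(all_snp))
  for (i in rev(seq_len(k))) {
    mi <- match(scans[[i]]$snp, all_snp)
    chr[mi] <- scans[[i]]$chr
    pos[mi] <- scans[[i]]$pos
  }

  subsets <- if (is.null(eligibility)) {
    list(seq_len(k))  # calibration form: one combined test per marker
  } else {
    unlist(lapply(2:k, function(s) {
      utils::combn(seq_len(k), s, simplify = FALSE)
    }), recursive = FALSE)
  }

  long <- list()
  for (S in subsets) {
    pS <- P[, S, drop = FALSE]
    if (is.null(eligibility)) {
      elig <- rowSums(is.na(pS)) == 0
    } else {
      elig <- rowSums(pS < eligibility) == length(S)  # NA -> not eligible
      elig[is.na(elig)] <- FALSE
    }
    if (!any(elig)) next
    idx <- which(elig)
    RS <- R[S, S, drop = FALSE]
    par <- fisher_null_params(RS, two_sided, cov_method, moments)
    T_stat <- rowSums(-2 * log(pS[idx, , drop = FALSE]))
    pcma <- stats::pgamma(pmax(T_stat - par$a, 0) / par$b,
                          shape = par$s, lower.tail = FALSE)
    df <- data.frame(snp = all_snp[idx], chr = chr[idx], pos = pos[idx],
                     subset = paste(trait_names[S], collapse = "_"),
                     size = length(S),
                     t = T_stat, c = par$c, f = par$f, p_cma = pcma,
                     stringsAsFactors = FALSE)
    for (i in seq_len(k)) {
      df[[paste0("p_", trait_names[i])]] <-
        if (i %in% S) P[idx, i] else NA_real_
    }
    long[[length(long) + 1]] <- df
  }
  if (length(long) == 0) {
    empty <- data.frame(snp = character(0), chr = integer(0),
                        pos = numeric(0), subset = character(0),
                        size = integer(0), t = numeric(0), c = numeric(0),
                        f = numeric(0), p_cma = numeric(0))
    for (tn in trait_names) empty[[paste0("p_", tn)]] <- numeric(0)
    class(empty) <- c("cma_table", "data.frame")
    attr(empty, "subsets") <- empty
    return(empty)
  }
  long <- do.call(rbind, long)
  # headline: minimal CMA p; ties to larger subset, then earlier label
  ord <- order(long$snp, long$p_cma, -long$size, long$subset)
  lo <- long[ord, , drop = FALSE]
  head_tab <- lo[!duplicated(lo$snp), , drop = FALSE]
  head_tab <- head_tab[order(head_tab$chr, head_tab$pos), , drop = FALSE]
  rownames(head_tab) <- NULL
  head_tab$size <- NULL
  class(head_tab) <- c("cma_table", "data.frame")
  long$size <- NULL
  attr(head_tab, "subsets") <- long
  head_tab
}
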