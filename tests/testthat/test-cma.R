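test_that("dichotomization counts behave under concordance and trimming", {
  s <- correlated_null_scans(2000, 0, seed = 1)[[1]]
  ct <- dichotomize_scans(s$p, s$p, trim = 0)
  expect_equal(ct$b, 0); expect_equal(ct$c, 0)
  expect_equal(ct$a + ct$d, 2000)
  # independent scans: quadrants near m/4
  sc <- correlated_null_scans(40000, 0, seed = 2)
  ct2 <- dichotomize_scans(sc[[1]]$p, sc[[2]]$p, trim = 0)
  expect_lt(abs(ct2$a / 40000 - 0.25), 0.01)
  expect_lt(abs(ct2$d / 40000 - 0.25), 0.01)
  # trim removes strong signals; trim = 0 conserves everything
  p1 <- c(1e-6, runif(99)); p2 <- c(1e-6, runif(99))
  expect_equal(dichotomize_scans(p1, p2, trim = 1e-4)$n_used, 99)
  expect_equal(dichotomize_scans(p1, p2, trim = 0)$n_used, 100)
  expect_error(dichotomize_scans(numeric(0), numeric(0)), "shared markers")
})

test_that("tetrachoric estimator handles analytic special cases", {
  expect_equal(tetrachoric(25, 25, 25, 25), 0, tolerance = 1e-6)
  expect_equal(tetrachoric(50, 0, 0, 50), 0.999)   # perfect association
  expect_equal(tetrachoric(0, 50, 50, 0), -0.999)
  expect_error(tetrachoric(0, 0, 3, 5), "degenerate")
  expect_error(tetrachoric(-1, 2, 3, 4), "nonnegative")
  # cosine approximation at independence
  expect_equal(tetrachoric(25, 25, 25, 25, estimator = "cosine"), 0,
               tolerance = 1e-6)
})

test_that("ML tetrachoric recovers the latent correlation from counts", {
  set.seed(3)
  m <- 1e5
  rho <- 0.5
  z1 <- rnorm(m); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
  x1 <- z1 > 0; x2 <- z2 > 0
  est <- tetrachoric(sum(x1 & x2), sum(x1 & !x2), sum(!x1 & x2),
                     sum(!x1 & !x2))
  expect_lt(abs(est - 0.5), 0.02)
})

test_that("two-sided orthant estimator recovers |rho| from two-sided p", {
  sc <- correlated_null_scans(2e5, 0.7, seed = 4)
  ct <- dichotomize_scans(sc[[1]]$p, sc[[2]]$p)
  est <- tetrachoric_twosided(ct$a, ct$b, ct$c, ct$d)
  expect_lt(abs(est - 0.7), 0.02)
  # sign is not identifiable: negative rho gives the same magnitude
  sc2 <- correlated_null_scans(2e5, -0.7, seed = 5)
  ct2 <- dichotomize_scans(sc2[[1]]$p, sc2[[2]]$p)
  expect_lt(abs(tetrachoric_twosided(ct2$a, ct2$b, ct2$c, ct2$d) - 0.7),
            0.02)
})

test_that("exact Fisher-term covariance reproduces the cubic approximation", {
  for (r in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    expect_equal(fisher_cov(r, two_sided = FALSE),
                 fisher_cov(r, method = "kost"), tolerance = 2e-3)
  }
  expect_equal(fisher_cov(0), 0, tolerance = 1e-10)
  expect_equal(fisher_cov(1), 4)       # duplicated scan: var of chi2_2
  expect_equal(fisher_cov(-1), 4)      # two-sided: even in rho
})

test_that("Brown combination matches its chi-square oracle values", {
  b <- brown_combine(c(0.05, 0.05), diag(2))
  expect_equal(b$T, -4 * log(0.05), tolerance = 1e-9)
  expect_equal(b$p, stats::pchisq(-4 * log(0.05), 4, lower.tail = FALSE))
  expect_equal(b$p, 0.0175, tolerance = 2e-3)
  # independence: Brown is Fisher's chi-square exactly, any k
  p3 <- c(0.2, 0.01, 0.6)
  b3 <- brown_combine(p3, diag(3))
  expect_equal(b3$p,
               stats::pchisq(sum(-2 * log(p3)), 6, lower.tail = FALSE))
  expect_error(brown_combine(c(0, 0.5), diag(2)), "0, 1")
  expect_error(brown_combine(c(0.5, 0.5), matrix(c(1, 1.2, 1.2, 1), 2)),
               "rho")
})

test_that("duplicate scans at rho = 1 return the single-scan p exactly", {
  R1 <- matrix(c(1, 1, 1, 1), 2)
  for (q in c(0.5, 0.05, 1e-6)) {
    expect_equal(brown_combine(c(q, q), R1)$p, q, tolerance = 1e-12)
    expect_equal(stouffer_combine(c(q, q), c(1, 1), R1)$p, q,
                 tolerance = 1e-9)
  }
})

test_that("Brown with estimated correlation matches Monte-Carlo truth", {
  set.seed(6)
  m <- 1e6
  rho <- 0.5
  z1 <- rnorm(m); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
  T_mc <- -2 * (log(2 * pnorm(-abs(z1))) + log(2 * pnorm(-abs(z2))))
  b <- brown_combine(c(0.01, 0.01), matrix(c(1, rho, rho, 1), 2))
  truth <- mean(T_mc >= -4 * log(0.01))
  expect_lt(abs(b$p - truth), 0.1 * truth)
})

test_that("combined p is nondecreasing in the scan correlation", {
  p <- c(0.01, 0.02)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  pv <- vapply(grid, function(r) {
    brown_combine(p, matrix(c(1, r, r, 1), 2))$p
  }, numeric(1))
  expect_true(all(diff(pv) > 0))
})

test_that("Stouffer combiner matches its normal oracle and cancels", {
  p196 <- 2 * pnorm(-1.96)
  s <- stouffer_combine(c(p196, p196), c(1, 1), diag(2))
  expect_equal(s$Z, 2 * 1.96 / sqrt(2), tolerance = 1e-9)
  expect_equal(s$p, 2 * pnorm(-2.772), tolerance = 1e-3)
  s0 <- stouffer_combine(c(p196, p196), c(1, -1), diag(2))
  expect_equal(s0$Z, 0)
  expect_equal(s0$p, 1)
})

test_that("scan correlation is near zero for disjoint null scans", {
  sc <- correlated_null_scans(40000, 0, seed = 7)
  est <- scan_correlation(sc)
  expect_lt(abs(est$rho[1, 2]), 0.05)
})

test_that("duplicated scans estimate correlation at the cap", {
  s <- correlated_null_scans(5000, 0, seed = 8)[[1]]
  est <- scan_correlation(list(a = s, b = s))
  expect_gte(est$rho[1, 2], 0.99)
})

test_that("scan correlation increases with sample overlap", {
  # overlap f of shared samples gives z-correlation ~ f * rho_trait;
  # emulate by mixing correlated and independent z components
  rho_trait <- 0.7
  est <- vapply(c(0, 0.5, 1), function(f) {
    sc <- correlated_null_scans(50000, f * rho_trait,
                                seed = 9 + round(10 * f))
    scan_correlation(sc)$rho[1, 2]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_lt(abs(est[3] - 0.7), 0.05)
})

test_that("per-marker subset enumeration follows the eligibility rule", {
  mk <- function(p) data.frame(snp = c("m1", "m2"), chr = 1L,
                               pos = c(100L, 200L), p = p,
                               stringsAsFactors = FALSE)
  scans <- list(egfr_cr = mk(c(1e-9, 0.5)),
                egfr_cys = mk(c(1e-6, 0.2)),
                srage = mk(c(0.5, 0.9)))
  R <- diag(3)
  out <- cma_scan(scans, R, eligibility = 0.01)
  # m1: sRAGE ineligible, headline subset is the eGFR pair
  expect_equal(nrow(out), 1)
  expect_equal(out$subset, "egfr_cr_egfr_cys")
  expect_true(is.na(out$p_srage))
  # m2: no eligible subset anywhere
  expect_false("m2" %in% out$snp)
  # long output holds exactly the evaluated subsets
  expect_equal(attr(out, "subsets")$subset, "egfr_cr_egfr_cys")
})

test_that("headline record takes the smallest combined p-value", {
  mk <- function(p) data.frame(snp = "m1", chr = 1L, pos = 100L, p = p,
                               stringsAsFactors = FALSE)
  scans <- list(a = mk(1e-8), b = mk(1e-7), c = mk(5e-3))
  out <- cma_scan(scans, diag(3), eligibility = 0.01)
  long <- attr(out, "subsets")
  expect_equal(out$p_cma, min(long$p_cma))
  expect_equal(nrow(long), 4)  # three pairs and the triple
})
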