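test_that("trait preparation validates inputs and builds the design", {
  covar <- data.frame(age = c(50, 60), sex = c("male", "female"),
                      pc1 = c(0.1, -0.2))
  pt <- prepare_trait(c(exp(1), exp(1)), covar)
  expect_equal(pt$y, c(1, 1))
  expect_true("age2" %in% colnames(pt$X) ||
                any(grepl("age2", colnames(pt$X))))
  expect_error(prepare_trait(c(1, -2), covar, ids = c("a", "b")), "b")
  covar_na <- covar; covar_na$age[2] <- NA
  expect_error(prepare_trait(c(1, 2), covar_na, ids = c("a", "b")),
               "missing covariate.*b")
  covar_bad <- covar; covar_bad$age2 <- c(2500, 9999)
  expect_error(prepare_trait(c(1, 2), covar_bad), "inconsistent")
})

test_that("with identity kinship the mixed model collapses to OLS", {
  set.seed(1)
  n <- 120
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("i", "x1", "x2")
  y <- drop(X %*% c(1, 0.5, -0.3)) + rnorm(n)
  fit <- lmm_reml_fit(y, X, diag(n) / 2)
  ols <- stats::lm(y ~ X - 1)
  expect_equal(unname(fit$beta), unname(stats::coef(ols)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(ols)))),
               tolerance = 1e-6)
  # full scan: per-variant beta and SE match OLS, p from the same z
  ped <- founder_pedigree(n)
  g <- simulate_genotypes(ped, m = 40, maf = 0.3, seed = 2)
  assoc <- lmm_association(fit, g)
  i <- which(assoc$snp == g$map$snp[5])
  ref <- stats::lm(y ~ X - 1 + g$dosage[, 5])
  b <- stats::coef(ref)[4]
  se <- sqrt(diag(stats::vcov(ref)))[4]
  expect_equal(assoc$beta[i], unname(b), tolerance = 1e-6)
  expect_equal(assoc$se[i], unname(se), tolerance = 1e-6)
  expect_equal(assoc$p[i], unname(2 * stats::pnorm(-abs(b / se))),
               tolerance = 1e-6)
})

test_that("REML matches a dense grid search on a toy problem", {
  set.seed(3)
  ped <- sib_pedigree()
  ped8 <- pedigree(
    c(ped$id, paste0("f", 1:4)),
    c(ped$father, rep(NA, 4)), c(ped$mother, rep(NA, 4)),
    c(ped$sex, rep(c("male", "female"), 2))
  )
  K <- build_kinship(ped8)
  n <- 8
  G <- 2 * K
  L <- t(chol(G + 1e-10 * diag(n)))
  y <- drop(L %*% rnorm(n)) * sqrt(0.8) + sqrt(0.2) * rnorm(n)
  X <- matrix(1, n, 1)
  fit <- lmm_reml_fit(y, X, K)
  ev <- eigen(G, symmetric = TRUE)
  reml_d <- function(d) {
    lam <- pmax(ev$values, 0)
    yr <- crossprod(ev$vectors, y)
    Xr <- crossprod(ev$vectors, X)
    w <- 1 / (lam + d)
    XtWX <- crossprod(Xr, w * Xr)
    beta <- solve(XtWX, crossprod(Xr, w * yr))
    r <- yr - Xr %*% beta
    s2 <- sum(w * r^2) / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi * s2) + sum(log(lam + d)) +
              determinant(XtWX)$modulus[1] + (n - 1))
  }
  grid <- seq(1e-3, 20, by = 1e-3)
  vals <- vapply(grid, reml_d, numeric(1))
  expect_gte(fit$loglik, max(vals) - 1e-6)
  if (fit$delta < 20) {
    expect_equal(fit$delta, grid[which.max(vals)], tolerance = 2e-3)
  }
})

test_that("non-PSD kinship beyond tolerance is an error", {
  K <- diag(4) / 2
  K[1, 2] <- K[2, 1] <- 0.9   # forces a clearly negative eigenvalue
  expect_error(lmm_reml_fit(rnorm(4), matrix(1, 4, 1), K),
               "positive semidefinite")
})

test_that("association is calibrated under the null on families", {
  cohort <- simulate_cohort(n_fam = 25, m = 5000,
                            spec = effect_spec(h2 = 0.3), seed = 13)
  covar <- cohort$phen$phenotypes[, c("age", "sex", "center", "pc1")]
  scan <- gwas_scan(cohort$traits$egfr_cys, covar, cohort$geno,
                    cohort$kinship, scan_id = "egfr_cys")
  expect_lt(abs(mean(scan$p < 0.05) - 0.05), 0.01)
  expect_gt(attr(scan, "lambda_gc"), 0.9)
  expect_lt(attr(scan, "lambda_gc"), 1.1)
})

test_that("an injected 1-SD effect at common MAF reaches genome-wide p", {
  ped <- founder_pedigree(1000)
  K <- build_kinship(ped)
  hits <- replicate(10, {
    seed <- sample.int(1e6, 1)
    g <- simulate_genotypes(ped, m = 5, maf = 0.3, seed = seed)
    y <- 1 * scale(g$dosage[, 3], scale = FALSE) + rnorm(1000)
    fit <- lmm_reml_fit(drop(y), matrix(1, 1000, 1), K)
    a <- lmm_association(fit, g)
    a$p[a$snp == g$map$snp[3]] < 5e-8
  })
  expect_gte(mean(hits), 0.9)
})

test_that("allele relabelling flips the sign but not the p-value", {
  set.seed(5)
  ped <- founder_pedigree(200)
  g <- simulate_genotypes(ped, m = 10, maf = 0.3, seed = 6)
  y <- rnorm(200)
  fit <- lmm_reml_fit(y, matrix(1, 200, 1), build_kinship(ped))
  a1 <- lmm_association(fit, g)
  g2 <- g
  g2$dosage <- 2 - g$dosage
  a2 <- lmm_association(fit, g2)
  expect_equal(a2$beta, -a1$beta)
  expect_equal(a2$p, a1$p)
})

test_that("p-values are invariant to affine rescaling of the trait", {
  set.seed(7)
  cohort <- simulate_cohort(n_fam = 6, m = 50, seed = 21)
  K <- cohort$kinship
  y <- log(cohort$traits$egfr_cr)
  X <- matrix(1, length(y), 1)
  f1 <- lmm_reml_fit(y, X, K)
  f2 <- lmm_reml_fit(3 + 2.5 * y, X, K)
  a1 <- lmm_association(f1, cohort$geno)
  a2 <- lmm_association(f2, cohort$geno)
  expect_equal(a2$p, a1$p, tolerance = 1e-9)
  expect_equal(a2$beta, 2.5 * a1$beta, tolerance = 1e-9)
})

test_that("genomic lambda matches its closed forms", {
  expect_equal(genomic_lambda(rep(0.5, 10)), 1)
  p1 <- stats::pchisq(1, 1, lower.tail = FALSE)  # 0.31731
  expect_equal(genomic_lambda(rep(p1, 10)), 1 / 0.4549364,
               tolerance = 1e-4)
  expect_equal(genomic_lambda(rep(p1, 10)), 2.198, tolerance = 1e-3)
  set.seed(8)
  expect_equal(genomic_lambda(runif(1e5)), 1, tolerance = 0.02)
  expect_error(genomic_lambda(c(0.5, 0)), "0, 1")
  expect_error(genomic_lambda(numeric(0)), "empty")
})
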