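test_that("null spec gives uncorrelated latent traits", {
  ped <- founder_pedigree(2000)
  g <- simulate_genotypes(ped, m = 10, maf = 0.3, seed = 1)
  K <- build_kinship(ped)
  sp <- effect_spec(C = diag(3), h2 = 0)
  ph <- simulate_phenotypes(g, K, sp, seed = 2)
  cc <- stats::cor(ph$latent)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("latent correlations recover the target structure", {
  ped <- founder_pedigree(2000)
  g <- simulate_genotypes(ped, m = 10, maf = 0.3, seed = 1)
  K <- build_kinship(ped)
  ph <- simulate_phenotypes(g, K, effect_spec(h2 = 0), seed = 3)
  cc <- stats::cor(ph$latent)
  expect_lt(abs(cc[1, 2] - 0.70), 0.05)
  expect_lt(abs(cc[1, 3] + 0.25), 0.05)
  expect_lt(abs(cc[2, 3] + 0.30), 0.05)
})

test_that("latent correlations converge to the spec with heritability", {
  # polygenic and residual components share the correlation, so the
  # total latent correlation stays at C for any h2
  ped <- simulate_pedigree(n_fam = 360, seed = 4)  # ~5000 individuals
  g <- simulate_genotypes(ped, m = 5, maf = 0.3, seed = 4)
  K <- build_kinship(ped)
  ph <- simulate_phenotypes(g, K, effect_spec(h2 = 0.4), seed = 5)
  expect_gte(nrow(ph$latent), 5000)
  cc <- stats::cor(ph$latent)
  C <- default_trait_correlation()
  expect_lt(max(abs(cc - C)), 0.03)
})

test_that("invalid correlation matrices are rejected", {
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3)
  expect_error(effect_spec(C = bad), "positive definite")
  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(effect_spec(C = asym), "symmetric")
  expect_error(effect_spec(h2 = 1.2), "h2")
})

test_that("concentrations are positive and phenotypes reproducible", {
  ped <- simulate_pedigree(n_fam = 5, seed = 6)
  g <- simulate_genotypes(ped, m = 20, maf = 0.3, seed = 6)
  K <- build_kinship(ped)
  p1 <- simulate_phenotypes(g, K, seed = 11)
  p2 <- simulate_phenotypes(g, K, seed = 11)
  expect_identical(p1$phenotypes, p2$phenotypes)
  expect_true(all(p1$phenotypes$scr > 0))
  expect_true(all(p1$phenotypes$scys > 0))
  expect_true(all(p1$phenotypes$srage > 0))
  expect_true(all(p1$phenotypes$age >= 24 & p1$phenotypes$age <= 110))
})

test_that("a strong pleiotropic variant is detected by all three scans", {
  ped <- founder_pedigree(2000)
  g <- simulate_genotypes(ped, m = 50, maf = 0.3, seed = 7)
  K <- build_kinship(ped)
  beta <- data.frame(variant = 10, trait = c(1, 2, 3),
                     beta = c(0.5, 0.5, 0.5))
  ph <- simulate_phenotypes(g, K, effect_spec(beta = beta, h2 = 0),
                            seed = 8)
  covar <- ph$phenotypes[, c("age", "sex", "center", "pc1")]
  traits <- derive_traits(ph$phenotypes)
  for (tr in c("egfr_cr", "egfr_cys", "srage")) {
    scan <- gwas_scan(traits[[tr]], covar, g, K, scan_id = tr)
    expect_lt(scan$p[scan$snp == g$map$snp[10]], 0.01)
  }
})

test_that("derived traits apply the CKD-EPI algebra consistently", {
  ped <- simulate_pedigree(n_fam = 4, seed = 9)
  g <- simulate_genotypes(ped, m = 10, maf = 0.3, seed = 9)
  K <- build_kinship(ped)
  ph <- simulate_phenotypes(g, K, seed = 10)
  tr <- derive_traits(ph$phenotypes)
  i <- 7
  expect_equal(tr$egfr_cr[i],
               egfr_creatinine(ph$phenotypes$scr[i], ph$phenotypes$age[i],
                               ph$phenotypes$sex[i]))
  expect_equal(tr$ckd_cr, tr$egfr_cr < 60)
})
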