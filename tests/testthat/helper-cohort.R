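# Shared fixtures and independent oracles, built in code at test time.

# trio: two unrelated founders and one child
trio_pedigree <- function() {
  pedigree(c("p1", "p2", "o1"), c(NA, NA, "p1"), c(NA, NA, "p2"),
           c("male", "female", "female"))
}

# nuclear family with two full sibs
sib_pedigree <- function() {
  pedigree(c("p1", "p2", "s1", "s2"), c(NA, NA, "p1", "p1"),
           c(NA, NA, "p2", "p2"),
           c("male", "female", "female", "male"))
}

# founders-only pedigree of n unrelated individuals
founder_pedigree <- function(n) {
  pedigree(paste0("f", seq_len(n)), rep(NA, n), rep(NA, n),
           rep(c("male", "female"), length.out = n))
}

# Monte-Carlo gene-dropping estimate of the full kinship matrix: founders
# get unique allele labels, children inherit one random allele per
# parent; the kinship of (i, j) is the probability that one allele drawn
# from each is identical by descent, averaged over replicates.
gene_drop_kinship <- function(ped, n_rep = 1e4, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  acc <- matrix(0, n, n)
  founder <- is.na(ped$father)
  for (r in seq_len(n_rep)) {
    h <- matrix(0L, n, 2)
    lab <- 0L
    for (i in seq_len(n)) {
      if (founder[i]) {
        h[i, ] <- c(lab + 1L, lab + 2L)
        lab <- lab + 2L
      } else {
        fi <- idx[[ped$father[i]]]
        mi <- idx[[ped$mother[i]]]
        h[i, 1] <- h[fi, sample.int(2, 1)]
        h[i, 2] <- h[mi, sample.int(2, 1)]
      }
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        s <- (h[i, 1] == h[j, 1]) + (h[i, 1] == h[j, 2]) +
          (h[i, 2] == h[j, 1]) + (h[i, 2] == h[j, 2])
        acc[i, j] <- acc[i, j] + s / 4
      }
    }
  }
  acc <- acc / n_rep
  acc[lower.tri(acc)] <- t(acc)[lower.tri(acc)]
  dimnames(acc) <- list(ped$id, ped$id)
  acc
}

# correlated uniform p-value pair via latent bivariate normal z
correlated_null_scans <- function(m, rho, seed = 1) {
  set.seed(seed)
  z1 <- stats::rnorm(m)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
  list(
    data.frame(snp = sprintf("v%06d", seq_len(m)), chr = 1L,
               pos = seq_len(m), p = 2 * stats::pnorm(-abs(z1)),
               stringsAsFactors = FALSE),
    data.frame(snp = sprintf("v%06d", seq_len(m)), chr = 1L,
               pos = seq_len(m), p = 2 * stats::pnorm(-abs(z2)),
               stringsAsFactors = FALSE)
  )
}

# minimal valid scan table for io tests
toy_scan_table <- function(m = 5, seed = 1) {
  set.seed(seed)
  scan_table(data.frame(
    snp = sprintf("rs%d", seq_len(m)), chr = 1L,
    pos = seq_len(m) * 1000L, ea = "A", oa = "G",
    beta = stats::rnorm(m), se = stats::runif(m, 0.5, 1.5),
    p = stats::runif(m), mac = 20L + seq_len(m), maf = 0.1, n = 100L,
    stringsAsFactors = FALSE
  ), scan_id = "toy")
}
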