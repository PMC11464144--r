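#' Simulate genotype dosages through a pedigree
#'
#' Founder haplotypes are drawn Bernoulli(MAF) per allele (dosage
#' Binomial(2, MAF)); non-founders receive one allele from each parent by
#' Mendelian transmission. This reproduces the expected kinship structure
#' of the pedigree in the realized genotypes, including rare variants.
#'
#' @param ped a [pedigree()].
#' @param m number of variants.
#' @param maf per-variant minor allele frequency: a single value, a vector
#'   of length `m`, or a function `function(m)` returning `m` frequencies
#'   (a MAF spectrum). All values must lie in (0, 0.5].
#' @param seed integer seed.
#' @param chromosome,position optional variant coordinates; defaults place
#'   variants every 50 kb along chromosomes of 2000 variants each.
#' @return A list of class `"genotype_matrix"` with elements
#'   `dosage` (n x m integer matrix, rows named by individual id),
#'   `map` (data.frame: `snp`, `chr`, `pos`, `ea`, `oa`, `maf` nominal).
#' @export
simulate_genotypes <- function(ped, m, maf = 0.2, seed = 1,
                               chromosome = NULL, position = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (n == 0) stop("empty pedigree")
  if (m <= 0) stop("m must be positive")
  if (is.function(maf)) maf <- maf(m)
  maf <- rep_len(as.numeric(maf), m)
  if (any(maf <= 0) || any(maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  set.seed(seed)
  # haplotypes: two n x m 0/1 matrices, filled in pedigree order
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  idx <- stats::setNames(seq_len(n), ped$id)
  founder <- is.na(ped$father)
  nf <- sum(founder)
  h1[founder, ] <- matrix(stats::rbinom(nf * m, 1L, rep(maf, each = nf)), nf, m)
  h2[founder, ] <- matrix(stats::rbinom(nf * m, 1L, rep(maf, each = nf)), nf, m)
  for (i in which(!founder)) {
    fi <- idx[[ped$father[i]]]
    mi <- idx[[ped$mother[i]]]
    pick_f <- stats::rbinom(m, 1L, 0.5) == 1L
    pick_m <- stats::rbinom(m, 1L, 0.5) == 1L
    h1[i, ] <- ifelse(pick_f, h1[fi, ], h2[fi, ])
    h2[i, ] <- ifelse(pick_m, h1[mi, ], h2[mi, ])
  }
  dosage <- h1 + h2
  rownames(dosage) <- ped$id
  if (is.null(chromosome)) chromosome <- ((seq_len(m) - 1L) %/% 2000L) + 1L
  if (is.null(position)) {
    position <- (((seq_len(m) - 1L) %% 2000L) + 1L) * 50000L
  }
  map <- data.frame(
    snp = sprintf("var%06d", seq_len(m)),
    chr = chromosome, pos = position,
    ea = "A", oa = "G", maf = maf,
    stringsAsFactors = FALSE
  )
  colnames(dosage) <- map$snp
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' Observed minor allele count per variant
#' @param dosage n x m dosage matrix in \{0,1,2\}.
#' @return integer vector of length m: `min(ac, 2n - ac)`.
#' @export
minor_allele_count <- function(dosage) {
  ac <- colSums(dosage)
  as.integer(pmin(ac, 2 * nrow(dosage) - ac))
}

#' Filter variants on minor allele count and allele type
#'
#' Keeps a variant iff its minor allele count is at least `threshold`
#' (i.e. variants with MAC < threshold are excluded) and, when allele
#' strings are supplied, both alleles are single nucleotides (insertions,
#' deletions and structural alleles are excluded).
#'
#' @param dosage n x m dosage matrix.
#' @param threshold minimum minor allele count retained (default 20).
#' @param ea,oa optional allele strings of length m; variants with
#'   `nchar() != 1` in either allele are dropped.
#' @return integer index of retained variants.
#' @export
mac_filter <- function(dosage, threshold = 20, ea = NULL, oa = NULL) {
  mac <- minor_allele_count(dosage)
  keep <- mac >= threshold
  if (!is.null(ea)) keep <- keep & nchar(ea) == 1L
  if (!is.null(oa)) keep <- keep & nchar(oa) == 1L
  which(keep)
}

#' A mixed MAF spectrum with common and rare variants
#'
#' Returns a function usable as the `maf` argument of
#' [simulate_genotypes()]: a fraction `rare_fraction` of variants get
#' rare frequencies drawn uniformly from `rare_range` (default below
#' 0.5%), the rest get Uniform(0.05, 0.5) common frequencies.
#'
#' @param rare_fraction fraction of rare variants.
#' @param rare_range range of rare MAFs.
#' @return function(m) -> numeric vector of length m.
#' @export
maf_spectrum <- function(rare_fraction = 0.2, rare_range = c(0.001, 0.005)) {
  force(rare_fraction); force(rare_range)
  function(m) {
    rare <- stats::runif(m) < rare_fraction
    out <- stats::runif(m, 0.05, 0.5)
    out[rare] <- stats::runif(sum(rare), rare_range[1], rare_range[2])
    out
  }
}
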