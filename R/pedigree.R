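#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with one row per individual. Founders have
#' missing parent ids (`NA` or `""`). Validation checks that parent ids
#' resolve, that sexes of parents are consistent (fathers male, mothers
#' female), and that no individual is its own ancestor.
#'
#' @param id character vector of individual ids (unique).
#' @param father,mother character vectors of parent ids; `NA` for founders.
#'   An individual must have either both parents or neither.
#' @param sex character vector, `"male"` or `"female"`.
#' @param family optional character vector of family ids; defaults to a
#'   single family `"F1"`.
#' @return A `data.frame` of class `"pedigree"` with columns
#'   `id`, `father`, `mother`, `sex`, `family`, topologically ordered so
#'   that parents precede children.
#' @examples
#' ped <- pedigree(c("p1", "p2", "o1"), c(NA, NA, "p1"), c(NA, NA, "p2"),
#'                 c("male", "female", "female"))
#' @export
pedigree <- function(id, father, mother, sex, family = NULL) {
  id <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  father[!is.na(father) & father == ""] <- NA_character_
  mother[!is.na(mother) & mother == ""] <- NA_character_
  if (anyDuplicated(id)) {
    stop("duplicate individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (length(father) != length(id) || length(mother) != length(id) ||
      length(sex) != length(id)) {
    stop("id, father, mother and sex must have equal length")
  }
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female' for every individual")
  }
  if (any(is.na(father) != is.na(mother))) {
    bad <- id[is.na(father) != is.na(mother)]
    stop("individuals with exactly one known parent: ",
         paste(bad, collapse = ", "))
  }
  known <- stats::setNames(sex, id)
  for (p in stats::na.omit(unique(father))) {
    if (!p %in% id) stop("father id not in pedigree: ", p)
    if (known[[p]] != "male") stop("father is not male: ", p)
  }
  for (p in stats::na.omit(unique(mother))) {
    if (!p %in% id) stop("mother id not in pedigree: ", p)
    if (known[[p]] != "female") stop("mother is not female: ", p)
  }
  if (is.null(family)) family <- rep("F1", length(id))
  ped <- data.frame(id = id, father = father, mother = mother,
                    sex = sex, family = as.character(family),
                    stringsAsFactors = FALSE)
  ped <- ped[pedigree_order(ped), , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Topological order (parents before children); errors on cycles naming an
# individual on the cycle.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  depth <- rep(NA_integer_, n)
  gen <- function(i, stack) {
    if (!is.na(depth[i])) return(depth[i])
    if (ped$id[i] %in% stack) {
      stop("cycle in pedigree involving individual ", ped$id[i])
    }
    f <- ped$father[i]
    if (is.na(f)) {
      d <- 0L
    } else {
      stack2 <- c(stack, ped$id[i])
      d <- 1L + max(gen(idx[[f]], stack2), gen(idx[[ped$mother[i]]], stack2))
    }
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) gen(i, character(0))
  order(depth, seq_len(n))
}

#' Number of individuals in a pedigree
#' @param ped a [pedigree()].
#' @return integer count.
#' @export
n_individuals <- function(ped) nrow(ped)

#' Expected kinship matrix from a pedigree
#'
#' Computes the matrix of expected kinship coefficients \eqn{\phi_{ij}}
#' (probability that two alleles, one sampled from each individual, are
#' identical by descent) by the standard recursion over a
#' parents-before-children ordering. Founders are assumed unrelated and
#' non-inbred, so the diagonal is 0.5 for founders and off-diagonals are
#' e.g. 0.25 for parent-offspring and full sibs.
#'
#' Convention: this function returns kinship \eqn{\phi}; the linear mixed
#' model uses the numerator relationship matrix \eqn{2\phi} (see
#' [lmm_reml_fit()]), which is the only place the factor 2 is applied.
#'
#' @param ped a [pedigree()].
#' @return An n x n symmetric matrix with dimnames set to individual ids,
#'   in pedigree (topological) order.
#' @examples
#' ped <- pedigree(c("p1", "p2", "o1"), c(NA, NA, "p1"), c(NA, NA, "p2"),
#'                 c("male", "female", "female"))
#' build_kinship(ped)["p1", "o1"]  # 0.25
#' @export
build_kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    f <- ped$father[i]
    m <- ped$mother[i]
    if (is.na(f)) {
      K[i, i] <- 0.5
    } else {
      fi <- idx[[f]]; mi <- idx[[m]]
      K[i, i] <- 0.5 + 0.5 * K[fi, mi]
      for (j in seq_len(i - 1L)) {
        # j precedes i, so j is not a descendant of i
        K[i, j] <- K[j, i] <- 0.5 * (K[j, fi] + K[j, mi])
      }
    }
  }
  # founders: relatedness to earlier individuals is 0 (already initialized)
  K
}

#' Simulate a multi-family three-generation pedigree
#'
#' Generates `n_fam` independent nuclear-extended families: a founder
#' couple, `n_children` offspring each married to an unrelated spouse,
#' and `n_grandchildren` children per offspring couple. This mirrors the
#' two-to-three-generation structure of family longevity cohorts.
#'
#' @param n_fam number of families.
#' @param n_children offspring per founder couple.
#' @param n_grandchildren children per offspring couple.
#' @param seed integer seed.
#' @return a [pedigree()].
#' @export
simulate_pedigree <- function(n_fam = 10, n_children = 3,
                              n_grandchildren = 2, seed = 1) {
  set.seed(seed)
  id <- character(0); fa <- character(0); mo <- character(0)
  sx <- character(0); fam <- character(0)
  add <- function(i, f, m, s, fm) {
    id <<- c(id, i); fa <<- c(fa, f); mo <<- c(mo, m)
    sx <<- c(sx, s); fam <<- c(fam, fm)
  }
  for (f in seq_len(n_fam)) {
    fm <- sprintf("F%02d", f)
    gp1 <- paste0(fm, "_gf"); gp2 <- paste0(fm, "_gm")
    add(gp1, NA, NA, "male", fm); add(gp2, NA, NA, "female", fm)
    for (c in seq_len(n_children)) {
      kid <- sprintf("%s_o%d", fm, c)
      ksex <- sample(c("male", "female"), 1)
      add(kid, gp1, gp2, ksex, fm)
      sp <- sprintf("%s_s%d", fm, c)
      spsex <- if (ksex == "male") "female" else "male"
      add(sp, NA, NA, spsex, fm)
      for (g in seq_len(n_grandchildren)) {
        gid <- sprintf("%s_o%d_g%d", fm, c, g)
        father <- if (ksex == "male") kid else sp
        mother <- if (ksex == "male") sp else kid
        add(gid, father, mother, sample(c("male", "female"), 1), fm)
      }
    }
  }
  pedigree(id, fa, mo, sx, fam)
}
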