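#' Apply the three pleiotropy criteria to CMA records
#'
#' A record passes iff (i) every contributing per-scan p-value is below
#' `gwas_cut`, (ii) the combined (CMA) p-value is below `cma_cut`, and
#' (iii) the CMA p-value is strictly smaller than the contributing
#' per-scan p-values — by default smaller than the *minimum* of them
#' (`rule = "min"`); `rule = "any"` requires it to beat at least one.
#' Contributing traits are the non-missing `p_<trait>` columns.
#'
#' @param records a `cma_table` (headline or long rows).
#' @param gwas_cut per-scan significance cut (default 0.01).
#' @param cma_cut combined significance cut (default 5e-8).
#' @param rule `"min"` (strict: CMA below every contributing p) or
#'   `"any"`.
#' @param require_individual apply criterion (i)? Gene-level scans use
#'   `FALSE` (their rule has no per-scan cut).
#' @return data.frame: `snp`, `pass`, `reasons` (semicolon-joined failing
#'   criteria, empty when passing).
#' @export
pleiotropy_filter <- function(records, gwas_cut = 0.01, cma_cut = 5e-8,
                              rule = c("min", "any"),
                              require_individual = TRUE) {
  rule <- match.arg(rule)
  pcols <- grep("^p_", names(records), value = TRUE)
  pcols <- setdiff(pcols, "p_cma")
  if (length(pcols) == 0) stop("no per-trait p columns found")
  pm <- as.matrix(records[, pcols, drop = FALSE])
  if (any(rowSums(!is.na(pm)) == 0)) stop("record with empty trait subset")
  n <- nrow(records)
  pass <- rep(TRUE, n)
  reasons <- rep("", n)
  add_reason <- function(idx, msg) {
    pass[idx] <<- FALSE
    reasons[idx] <<- ifelse(reasons[idx] == "", msg,
                            paste(reasons[idx], msg, sep = "; "))
  }
  if (require_individual) {
    bad <- which(apply(pm, 1, function(r) any(r[!is.na(r)] >= gwas_cut)))
    if (length(bad)) add_reason(bad, sprintf("individual p >= %g", gwas_cut))
  }
  bad <- which(records$p_cma >= cma_cut)
  if (length(bad)) add_reason(bad, sprintf("CMA p >= %g", cma_cut))
  best <- apply(pm, 1, function(r) {
    if (rule == "min") min(r, na.rm = TRUE) else max(r, na.rm = TRUE)
  })
  bad <- which(!(records$p_cma < best))
  if (length(bad)) {
    add_reason(bad, if (rule == "min") "CMA not smaller than best GWAS"
               else "CMA not smaller than any GWAS")
  }
  id <- if (!is.null(records$snp)) records$snp else records$gene
  if (is.null(id)) id <- rownames(records)
  data.frame(snp = id, pass = pass, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Greedy distance-based clumping of passing records into loci
#'
#' Repeatedly takes the record with the smallest CMA p-value as a lead
#' (ties broken toward the smaller genomic position), absorbs all records
#' on the same chromosome within half the window of the lead, and
#' recurses on the remainder. With the default 1 Mb window a locus spans
#' at most +/- 500 kb around its lead.
#'
#' @param records passing `cma_table` rows (must have `snp`, `chr`,
#'   `pos`, `subset`, `p_cma` and `p_<trait>` columns).
#' @param window locus width in bp (default 1e6; absorption radius is
#'   `window/2`).
#' @return data.frame of class `"locus_table"`: `lead_snp`, `chr`,
#'   `lead_pos`, `start`, `end`, `p_cma`, `subset`, per-trait p columns,
#'   `n_members`.
#' @export
clump <- function(records, window = 1e6) {
  pcols <- grep("^p_", names(records), value = TRUE)
  pcols <- setdiff(pcols, "p_cma")
  out <- list()
  rem <- records
  while (nrow(rem) > 0) {
    o <- order(rem$p_cma, rem$chr, rem$pos)
    lead <- rem[o[1], , drop = FALSE]
    member <- rem$chr == lead$chr & abs(rem$pos - lead$pos) <= window / 2
    mem <- rem[member, , drop = FALSE]
    loc <- data.frame(
      lead_snp = lead$snp, chr = lead$chr, lead_pos = lead$pos,
      start = min(mem$pos), end = max(mem$pos),
      p_cma = lead$p_cma, subset = lead$subset,
      n_members = nrow(mem), stringsAsFactors = FALSE
    )
    for (pc in pcols) loc[[pc]] <- lead[[pc]]
    out[[length(out) + 1]] <- loc
    rem <- rem[!member, , drop = FALSE]
  }
  if (length(out) == 0) {
    res <- data.frame(lead_snp = character(0), chr = integer(0),
                      lead_pos = numeric(0), start = numeric(0),
                      end = numeric(0), p_cma = numeric(0),
                      subset = character(0), n_members = integer(0))
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$chr, res$lead_pos), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("locus_table", "data.frame")
  res
}

#' Canonical trait-subset label of each locus
#'
#' Maps the contributing traits of the lead record (the non-missing
#' per-trait p-values) of each locus to one of `cr_cys_sRAGE`, `cr_cys`,
#' `cr_sRAGE`, `cys_sRAGE`.
#'
#' @param loci a `locus_table` (or any table with `p_egfr_cr`,
#'   `p_egfr_cys`, `p_srage` columns).
#' @return character vector of labels.
#' @export
classify_trait_set <- function(loci) {
  need <- c("p_egfr_cr", "p_egfr_cys", "p_srage")
  if (!all(need %in% names(loci))) {
    stop("expected columns ", paste(need, collapse = ", "))
  }
  has <- !is.na(as.matrix(loci[, need, drop = FALSE]))
  apply(has, 1, function(h) {
    parts <- c("cr", "cys", "sRAGE")[h]
    if (length(parts) < 2) stop("locus with fewer than two contributing traits")
    paste(parts, collapse = "_")
  })
}

#' Read a catalog of previously reported lead variants
#'
#' Two dialects: `"tab1"` — tab-delimited `CHR POS TRAIT SOURCE` with
#' 1-based positions; `"bed"` — 4-column BED (`chrom start end name`)
#' with 0-based starts, converted to 1-based positions.
#'
#' @param path file path.
#' @param dialect `"tab1"` or `"bed"`.
#' @param build genome build label recorded on the catalog.
#' @return data.frame `chr`, `pos`, `trait`, `source` with attributes
#'   `build` and `dialect`.
#' @export
read_catalog <- function(path, dialect = c("tab1", "bed"),
                         build = "GRCh38") {
  dialect <- match.arg(dialect)
  raw <- utils::read.table(path, header = (dialect == "tab1"), sep = "\t",
                           stringsAsFactors = FALSE)
  if (dialect == "tab1") {
    names(raw) <- tolower(names(raw))
    stopifnot(all(c("chr", "pos", "trait", "source") %in% names(raw)))
    cat_df <- raw[, c("chr", "pos", "trait", "source")]
  } else {
    stopifnot(ncol(raw) >= 4)
    cat_df <- data.frame(chr = raw[[1]], pos = raw[[2]] + 1L,
                         trait = raw[[4]], source = raw[[4]],
                         stringsAsFactors = FALSE)
  }
  cat_df$chr <- sub("^chr", "", as.character(cat_df$chr))
  if (any(cat_df$pos <= 0)) stop("catalog positions must be positive")
  attr(cat_df, "build") <- build
  attr(cat_df, "dialect") <- dialect
  cat_df
}

#' Annotate loci as novel or known against a catalog
#'
#' A locus is novel iff its lead variant is strictly more than
#' `distance` bp from every catalog entry on the same chromosome
#' (an entry at exactly `distance` makes the locus known). The nearest
#' entry and its distance are recorded.
#'
#' @param loci a `locus_table`.
#' @param catalog a catalog from [read_catalog()] (or an equivalent
#'   data.frame with a `build` attribute).
#' @param distance novelty radius in bp (default 5e5).
#' @param build genome build of the loci; must equal the catalog's.
#' @return `loci` with added columns `novel` (logical),
#'   `nearest_catalog` (source id or `NA`), `nearest_distance` (bp,
#'   `Inf` when the chromosome has no entries).
#' @export
annotate_novelty <- function(loci, catalog, distance = 5e5,
                             build = "GRCh38") {
  cat_build <- attr(catalog, "build")
  if (!is.null(cat_build) && !identical(cat_build, build)) {
    stop("genome build mismatch: loci ", build, " vs catalog ", cat_build)
  }
  chr_l <- sub("^chr", "", as.character(loci$chr))
  chr_c <- sub("^chr", "", as.character(catalog$chr))
  n <- nrow(loci)
  nearest <- rep(NA_character_, n)
  ndist <- rep(Inf, n)
  for (i in seq_len(n)) {
    onchr <- which(chr_c == chr_l[i])
    if (length(onchr)) {
      d <- abs(catalog$pos[onchr] - loci$lead_pos[i])
      j <- which.min(d)
      nearest[i] <- as.character(catalog$source[onchr[j]])
      ndist[i] <- d[j]
    }
  }
  loci$novel <- ndist > distance
  loci$nearest_catalog <- nearest
  loci$nearest_distance <- ndist
  loci
}

#' Summary report of a pleiotropy analysis
#'
#' Locus-level and (optionally) gene-level summary tables, counts by
#' trait subset, and the genomic-control factors of each input scan and
#' of the combined scan.
#'
#' @param loci a `locus_table` (possibly novelty-annotated); may have
#'   zero rows.
#' @param gene_results optional combined gene table (headline
#'   `cma_table` from the transcriptome scans).
#' @param lambdas optional named numeric vector of lambda_GC values.
#' @return list: `locus_table`, `gene_table`, `counts` (by subset
#'   label), `n_loci`, `n_novel`, `lambdas`.
#' @export
summarize_report <- function(loci, gene_results = NULL, lambdas = NULL) {
  counts <- integer(0)
  if (nrow(loci) > 0 &&
      all(c("p_egfr_cr", "p_egfr_cys", "p_srage") %in% names(loci))) {
    lab <- classify_trait_set(loci)
    counts <- table(factor(lab, levels = c("cr_cys_sRAGE", "cr_cys",
                                           "cr_sRAGE", "cys_sRAGE")))
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  list(
    locus_table = loci,
    gene_table = gene_results,
    counts = counts,
    n_loci = nrow(loci),
    n_novel = if ("novel" %in% names(loci)) sum(loci$novel) else NA_integer_,
    lambdas = lambdas
  )
}
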