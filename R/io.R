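#' Validate and class a per-scan association table
#'
#' @param df data.frame with columns `snp`, `chr`, `pos`, `ea`, `oa`,
#'   `beta`, `se`, `p`, `mac`, `maf`, `n`.
#' @param scan_id scan (trait) label stored as an attribute.
#' @return the validated data.frame, class `"scan_table"`.
#' @export
scan_table <- function(df, scan_id = "trait") {
  need <- c("snp", "chr", "pos", "ea", "oa", "beta", "se", "p", "mac",
            "maf", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("scan table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$snp)) {
    stop("duplicate marker ids: ",
         paste(utils::head(unique(df$snp[duplicated(df$snp)]), 3),
               collapse = ", "))
  }
  bad <- which(is.na(df$p) | df$p <= 0 | df$p > 1)
  if (length(bad)) {
    stop("p-value outside (0, 1] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(df$se <= 0)) stop("SE must be positive")
  if (any(df$pos <= 0)) stop("positions must be positive")
  df <- df[, need]
  class(df) <- c("scan_table", "data.frame")
  attr(df, "scan_id") <- scan_id
  df
}

#' Write a scan table to a tab-delimited file
#'
#' Header: `SNP CHR POS EA OA BETA SE P MAC MAF N`.
#'
#' @param tab a `scan_table`.
#' @param path output path.
#' @export
write_scan_table <- function(tab, path) {
  out <- tab
  names(out) <- c("SNP", "CHR", "POS", "EA", "OA", "BETA", "SE", "P",
                  "MAC", "MAF", "N")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and validate a scan table
#'
#' @param path tab-delimited file with header
#'   `SNP CHR POS EA OA BETA SE P MAC MAF N`.
#' @param scan_id scan label.
#' @return a `scan_table`.
#' @export
read_scan_table <- function(path, scan_id = "trait") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  expected <- c("SNP", "CHR", "POS", "EA", "OA", "BETA", "SE", "P",
                "MAC", "MAF", "N")
  if (!identical(names(df), expected)) {
    stop("malformed scan table header: expected ",
         paste(expected, collapse = " "))
  }
  names(df) <- c("snp", "chr", "pos", "ea", "oa", "beta", "se", "p",
                 "mac", "maf", "n")
  scan_table(df, scan_id = scan_id)
}

#' Write a gene-result table
#'
#' Header: `GENE CHR CYTOBAND Z_RAW P_RAW Z_CORR P_CORR N`; missing
#' values are written as `NA`.
#'
#' @param tab a `gene_result` data.frame from [twas_scan()].
#' @param path output path.
#' @export
write_gene_results <- function(tab, path) {
  out <- tab[, c("gene", "chr", "cytoband", "z_raw", "p_raw", "z_corr",
                 "p_corr", "n")]
  names(out) <- c("GENE", "CHR", "CYTOBAND", "Z_RAW", "P_RAW", "Z_CORR",
                  "P_CORR", "N")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a gene-result table
#' @param path tab-delimited file written by [write_gene_results()].
#' @return `gene_result` data.frame.
#' @export
read_gene_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  expected <- c("GENE", "CHR", "CYTOBAND", "Z_RAW", "P_RAW", "Z_CORR",
                "P_CORR", "N")
  if (!identical(names(df), expected)) {
    stop("malformed gene table header")
  }
  names(df) <- tolower(names(df))
  class(df) <- c("gene_result", "data.frame")
  df
}

#' Write a combined (CMA) table
#'
#' Header: `SNP CHR POS SUBSET P_CR P_CYS P_SRAGE T C F P_CMA`; per-trait
#' p-values absent from a record's subset are written as `NA`.
#'
#' @param tab a `cma_table` with per-trait columns `p_egfr_cr`,
#'   `p_egfr_cys`, `p_srage`.
#' @param path output path.
#' @export
write_cma_table <- function(tab, path) {
  out <- data.frame(
    SNP = tab$snp, CHR = tab$chr, POS = tab$pos, SUBSET = tab$subset,
    P_CR = tab$p_egfr_cr, P_CYS = tab$p_egfr_cys, P_SRAGE = tab$p_srage,
    T = tab$t, C = tab$c, F = tab$f, P_CMA = tab$p_cma
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a combined (CMA) table
#' @param path tab-delimited file written by [write_cma_table()].
#' @return `cma_table` data.frame.
#' @export
read_cma_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  expected <- c("SNP", "CHR", "POS", "SUBSET", "P_CR", "P_CYS",
                "P_SRAGE", "T", "C", "F", "P_CMA")
  if (!identical(names(df), expected)) stop("malformed CMA table header")
  out <- data.frame(
    snp = df$SNP, chr = df$CHR, pos = df$POS, subset = df$SUBSET,
    t = df$T, c = df$C, f = df$F, p_cma = df$P_CMA,
    p_egfr_cr = df$P_CR, p_egfr_cys = df$P_CYS, p_srage = df$P_SRAGE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cma_table", "data.frame")
  out
}

#' Write a between-scan correlation report
#'
#' The k x k correlation matrix followed by the per-pair 2x2 concordance
#' counts, tab-delimited.
#'
#' @param sc a `"scan_correlation"`.
#' @param path output path.
#' @export
write_scan_correlation <- function(sc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# estimator: ", sc$estimator,
                    if (sc$clipped) " (eigenvalue-clipped)" else ""), con)
  utils::write.table(round(sc$rho, 6), con, sep = "\t", quote = FALSE,
                     col.names = NA)
  writeLines("# pair\ta\tb\tc\td\tn_used", con)
  for (nm in names(sc$counts)) {
    ct <- sc$counts[[nm]]
    writeLines(paste(nm, ct$a, ct$b, ct$c, ct$d, ct$n_used, sep = "\t"),
               con)
  }
  invisible(path)
}

#' Published lead-variant worked example
#'
#' The 42 published novel pleiotropic lead variants for eGFRcr, eGFRcys
#' and sRAGE (GWAS p-values per contributing trait, combined CMA
#' p-value, cytoband and locus genes), bundled as a worked example for
#' the pleiotropy criteria and subset classification. Blank trait cells
#' in the published table are missing values.
#'
#' @return a `cma_table`-compatible data.frame with columns `snp`,
#'   `chr` (cytoband), `pos` (`NA`), `subset`, `locus_genes`,
#'   `p_egfr_cr`, `p_egfr_cys`, `p_srage`, `p_cma`.
#' @export
lead_variant_examples <- function() {
  path <- system.file("extdata", "lead_variants_kidney_srage.tsv",
                      package = "pleiocma", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "")
  out <- data.frame(
    snp = df$SNP, chr = df$CYTOBAND, pos = NA_real_, subset = df$SUBSET,
    locus_genes = df$LOCUS, p_egfr_cr = df$P_CR, p_egfr_cys = df$P_CYS,
    p_srage = df$P_SRAGE, p_cma = df$P_CMA, stringsAsFactors = FALSE
  )
  class(out) <- c("cma_table", "data.frame")
  out
}

#' Published pleiotropic-gene worked example
#'
#' The 17 published pleiotropic genes from the combined transcriptome
#' scans (one primary row per gene — the headline subset — plus the
#' additional published subset rows), bundled as a worked example for the
#' gene-level criteria.
#'
#' @return data.frame: `gene`, `cytoband`, `subset`, `primary`
#'   (logical), `p_egfr_cr`, `p_egfr_cys`, `p_srage`, `p_cma`.
#' @export
cma_gene_examples <- function() {
  path <- system.file("extdata", "cma_twas_genes.tsv",
                      package = "pleiocma", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "")
  data.frame(
    gene = df$GENE, cytoband = df$CYTOBAND, subset = df$SUBSET,
    primary = df$PRIMARY == 1,
    p_egfr_cr = df$P_CR, p_egfr_cys = df$P_CYS, p_srage = df$P_SRAGE,
    p_cma = df$P_CMA, stringsAsFactors = FALSE
  )
}

#' Pipeline configuration
#'
#' All thresholds of the analysis in one validated list. Unknown keys
#' are rejected.
#'
#' @param ... overrides of the defaults: `seed`, `gwas_cut` (0.01),
#'   `cma_cut` (5e-8), `twas_alpha` (0.05), `mac` (20), `min_cpm` (4),
#'   `max_fraction_low` (0.985), `novelty_distance` (5e5),
#'   `clump_window` (1e6), `trim` (1e-4), `dichotomize_cut` (0.5),
#'   `combiner` ("brown"/"stouffer"), `tetrachoric_estimator`
#'   ("ml-twosided"/"ml"/"cosine"), `n_fam`, `m`, `n_genes`, `h2`,
#'   `overlap`, `out_dir`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L, gwas_cut = 0.01, cma_cut = 5e-8, twas_alpha = 0.05,
    mac = 20, min_cpm = 4, max_fraction_low = 0.985,
    novelty_distance = 5e5, clump_window = 1e6, trim = 1e-4,
    dichotomize_cut = 0.5, combiner = "brown",
    tetrachoric_estimator = "ml-twosided",
    n_fam = 40, n_children = 3, n_grandchildren = 2,
    m = 2000, n_genes = 0, h2 = 0.3, overlap = 1,
    out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$gwas_cut > 0, cfg$gwas_cut < 1,
            cfg$cma_cut > 0, cfg$cma_cut < 1,
            cfg$mac >= 0, cfg$min_cpm >= 0,
            cfg$max_fraction_low > 0, cfg$max_fraction_low <= 1,
            cfg$novelty_distance > 0, cfg$clump_window > 0,
            cfg$trim >= 0, cfg$trim < cfg$dichotomize_cut,
            cfg$combiner %in% c("brown", "stouffer"),
            cfg$tetrachoric_estimator %in% c("ml-twosided", "ml", "cosine"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration (YAML)
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full synthetic-cohort pleiotropy pipeline
#'
#' Simulates a family cohort, runs the three kinship-LMM scans
#' (log eGFRcr, log eGFRcys, log sRAGE), estimates the between-scan null
#' correlation, combines per-marker p-values, applies the pleiotropy
#' criteria, clumps loci and (optionally) annotates novelty. When
#' `cfg$out_dir` is set, every stage's table and a provenance JSON are
#' written there.
#'
#' @param cfg a [pipeline_config()].
#' @param spec optional [effect_spec()] (default uses `cfg$h2` with the
#'   standard trait correlation and no variant effects).
#' @param catalog optional catalog for novelty annotation.
#' @return list: `scans`, `lambdas`, `correlation`, `cma` (headline
#'   table), `passing`, `loci`, `report`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), spec = NULL,
                         catalog = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(spec)) spec <- effect_spec(h2 = cfg$h2, overlap = cfg$overlap)
  cohort <- simulate_cohort(
    n_fam = cfg$n_fam, n_children = cfg$n_children,
    n_grandchildren = cfg$n_grandchildren, m = cfg$m,
    spec = spec, n_genes = cfg$n_genes, seed = cfg$seed
  )
  covar <- cohort$phen$phenotypes[, c("age", "sex", "center", "pc1")]
  traits <- cohort$traits
  n <- nrow(traits)
  scans <- list()
  trait_cols <- c(egfr_cr = "egfr_cr", egfr_cys = "egfr_cys",
                  srage = "srage")
  # overlapping subsets of one cohort: each scan analyses a shared block
  # plus its own private block, sized so shared / scan-size = overlap
  n_scan <- floor(n / (3 - 2 * cfg$overlap))
  n_shared <- round(cfg$overlap * n_scan)
  n_private <- n_scan - n_shared
  for (tn in names(trait_cols)) {
    if (cfg$overlap >= 1) {
      idx <- seq_len(n)
    } else {
      k_scan <- match(tn, names(trait_cols))
      priv <- n_shared + (k_scan - 1L) * n_private + seq_len(n_private)
      idx <- c(seq_len(n_shared), priv)
    }
    sub_geno <- list(dosage = cohort$geno$dosage[idx, , drop = FALSE],
                     map = cohort$geno$map)
    class(sub_geno) <- "genotype_matrix"
    scans[[tn]] <- gwas_scan(
      traits[[trait_cols[[tn]]]][idx], covar[idx, , drop = FALSE],
      sub_geno, cohort$kinship[idx, idx], scan_id = tn,
      mac_threshold = cfg$mac
    )
  }
  lambdas <- vapply(scans, function(s) attr(s, "lambda_gc"), numeric(1))
  sc <- scan_correlation(scans, cut = cfg$dichotomize_cut, trim = cfg$trim,
                         estimator = cfg$tetrachoric_estimator)
  cma <- cma_scan(scans, sc, eligibility = cfg$gwas_cut)
  cma_all <- cma_scan(scans, sc, eligibility = NULL)
  lambdas <- c(lambdas, cma = genomic_lambda(cma_all$p_cma))
  verdict <- if (nrow(cma) > 0) {
    pleiotropy_filter(cma, gwas_cut = cfg$gwas_cut, cma_cut = cfg$cma_cut)
  } else data.frame(snp = character(0), pass = logical(0),
                    reasons = character(0))
  passing <- cma[verdict$pass, , drop = FALSE]
  loci <- clump(passing, window = cfg$clump_window)
  if (!is.null(catalog) && nrow(loci) > 0) {
    loci <- annotate_novelty(loci, catalog,
                             distance = cfg$novelty_distance)
  }
  report <- summarize_report(loci, lambdas = lambdas)
  out <- list(scans = scans, lambdas = lambdas, correlation = sc,
              cma = cma, passing = passing, loci = loci, report = report)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tn in names(scans)) {
      write_scan_table(scans[[tn]],
                       file.path(cfg$out_dir, paste0("scan_", tn, ".tsv")))
    }
    write_scan_correlation(sc, file.path(cfg$out_dir,
                                         "scan_correlation.tsv"))
    if (nrow(cma) > 0) {
      write_cma_table(cma, file.path(cfg$out_dir, "cma.tsv"))
    }
    utils::write.table(loci, file.path(cfg$out_dir, "loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    prov <- list(config = unclass(cfg),
                 lambdas = as.list(lambdas),
                 rho = sc$rho,
                 package_version =
                   as.character(utils::packageVersion("pleiocma")))
    jsonlite::write_json(prov,
                         file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
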