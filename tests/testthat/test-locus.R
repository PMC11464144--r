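cma_row <- function(snp, chr, pos, p_cr, p_cys, p_sr, p_cma,
                    subset = "cr_cys") {
  n <- length(snp)
  data.frame(snp = snp, chr = chr, pos = pos,
             subset = rep_len(subset, n),
             t = rep(NA_real_, n), c = rep(NA_real_, n),
             f = rep(NA_real_, n), p_cma = p_cma,
             p_egfr_cr = rep_len(p_cr, n), p_egfr_cys = rep_len(p_cys, n),
             p_srage = rep_len(p_sr, n), stringsAsFactors = FALSE)
}

test_that("pleiotropy criteria are applied with their strict semantics", {
  rec <- rbind(
    cma_row("ok", 1, 1e6, 8.14e-9, 9.12e-5, NA, 6.99e-9),
    cma_row("weak_gwas", 1, 2e6, 0.02, 1e-4, NA, 1e-9),
    cma_row("cma_not_best", 1, 3e6, 1e-10, 1e-4, NA, 1e-9),
    cma_row("cma_above_cut", 1, 4e6, 1e-3, 1e-3, NA, 1e-7)
  )
  v <- pleiotropy_filter(rec)
  expect_equal(v$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(v$reasons[2], "individual p >= 0.01")
  expect_match(v$reasons[3], "not smaller than best")
  expect_match(v$reasons[4], "CMA p >= 5e-08")
  # "any" rule: beating one contributing p is enough
  v2 <- pleiotropy_filter(rec[3, ], rule = "any")
  expect_true(v2$pass)
})

test_that("all published lead variants pass and classify to the counts", {
  lv <- lead_variant_examples()
  expect_equal(nrow(lv), 42)
  v <- pleiotropy_filter(lv)
  expect_true(all(v$pass))
  lab <- classify_trait_set(lv)
  counts <- table(lab)
  expect_equal(unname(counts["cr_cys_sRAGE"]), 17)
  expect_equal(unname(counts["cr_cys"]), 19)
  expect_equal(unname(counts["cr_sRAGE"]), 2)
  expect_equal(unname(counts["cys_sRAGE"]), 4)
  # classification agrees with the published subset labels
  expect_equal(unname(lab), lv$subset)
})

test_that("published gene table replays against the Bonferroni rule", {
  ge <- cma_gene_examples()
  prim <- ge[ge$primary, ]
  expect_equal(nrow(prim), 17)
  thr <- bonferroni_threshold(18304)
  expect_equal(sum(prim$p_cma < thr), 17)
  single <- apply(prim[, c("p_egfr_cr", "p_egfr_cys", "p_srage")], 1,
                  function(r) any(r[!is.na(r)] < thr))
  expect_equal(sum(single), 4)
  # gene rule (no per-scan cut): LSP1 is the known strict-minimum
  # counter-case and must be the only failure among the primary rows
  v_min <- pleiotropy_filter(prim, cma_cut = thr,
                             require_individual = FALSE, rule = "min")
  expect_equal(prim$gene[!v_min$pass], "LSP1")
  v_any <- pleiotropy_filter(prim, cma_cut = thr,
                             require_individual = FALSE, rule = "any")
  expect_true(all(v_any$pass))
})

test_that("greedy clumping matches brute-force on the worked example", {
  rec <- rbind(
    cma_row("h1", 1, 1000000, 1e-4, 1e-4, NA, 1e-10),
    cma_row("h2", 1, 1400000, 1e-4, 1e-4, NA, 1e-9),
    cma_row("h3", 1, 3000000, 1e-4, 1e-4, NA, 1e-9)
  )
  loci <- clump(rec, window = 1e6)
  expect_equal(nrow(loci), 2)
  expect_setequal(loci$lead_snp, c("h1", "h3"))
  # single record: degenerate region
  l1 <- clump(rec[1, ])
  expect_equal(l1$start, l1$end)
  # equal p 100 kb apart: one locus, smaller position leads
  rec2 <- rbind(cma_row("a", 2, 500000, 1e-4, 1e-4, NA, 1e-9),
                cma_row("b", 2, 400000, 1e-4, 1e-4, NA, 1e-9))
  l2 <- clump(rec2)
  expect_equal(nrow(l2), 1)
  expect_equal(l2$lead_snp, "b")
})

test_that("clumping partitions records and is idempotent", {
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    rec <- cma_row(sprintf("s%03d", 1:n), sample(1:3, n, TRUE),
                   sample(1:5e7, n), 1e-4, 1e-4, NA,
                   10^-runif(n, 8, 14))
    loci <- clump(rec, window = 1e6)
    expect_equal(sum(loci$n_members), n)   # every record in one locus
    # brute-force membership check: each record within 500 kb of
    # exactly one lead after greedy removal
    expect_true(all(loci$end - loci$start <= 1e6))
    leads <- rec[match(loci$lead_snp, rec$snp), ]
    again <- clump(leads, window = 1e6)
    expect_equal(again$lead_snp, loci$lead_snp)
  }
})

test_that("novelty is strict beyond 500 kb on the same chromosome", {
  loci <- clump(cma_row("lead", 1, 1000000, 1e-4, 1e-4, NA, 1e-9))
  cat1 <- data.frame(chr = 1, pos = 1400000, trait = "egfr",
                     source = "known1")
  attr(cat1, "build") <- "GRCh38"
  a1 <- annotate_novelty(loci, cat1)
  expect_false(a1$novel)            # 400 kb away: known
  expect_equal(a1$nearest_distance, 400000)
  cat2 <- data.frame(chr = 1, pos = 1500000, trait = "egfr",
                     source = "exact")
  attr(cat2, "build") <- "GRCh38"
  expect_false(annotate_novelty(loci, cat2)$novel)  # exactly 500 kb: known
  cat3 <- data.frame(chr = 1, pos = 1500001, trait = "egfr",
                     source = "far")
  attr(cat3, "build") <- "GRCh38"
  expect_true(annotate_novelty(loci, cat3)$novel)
  # other chromosome or empty catalog: novel
  cat4 <- data.frame(chr = 2, pos = 1000000, trait = "x", source = "y")
  attr(cat4, "build") <- "GRCh38"
  expect_true(annotate_novelty(loci, cat4)$novel)
  empty <- data.frame(chr = integer(0), pos = integer(0),
                      trait = character(0), source = character(0))
  attr(empty, "build") <- "GRCh38"
  expect_true(annotate_novelty(loci, empty)$novel)
  attr(cat1, "build") <- "GRCh37"
  expect_error(annotate_novelty(loci, cat1), "build mismatch")
})

test_that("summary report counts subsets and handles empty input", {
  lv <- lead_variant_examples()
  v <- pleiotropy_filter(lv)
  fake_loci <- lv[v$pass, ]
  rep_out <- summarize_report(fake_loci)
  expect_equal(unname(rep_out$counts),
               c(17L, 19L, 2L, 4L))
  expect_equal(rep_out$n_loci, 42)
  empty <- clump(cma_row(character(0), integer(0), numeric(0),
                         numeric(0), numeric(0), numeric(0), numeric(0)))
  rep0 <- summarize_report(empty)
  expect_equal(rep0$n_loci, 0)
})
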