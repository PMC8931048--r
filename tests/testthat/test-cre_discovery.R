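test_that("co-marking, specificity and the distal rule", {
  genes <- gene_models("g1", "chr1", "+", 50000, 60000)
  atac_mt <- intervals(rep("chr1", 3), c(1000, 10000, 49000),
                       c(1500, 10400, 49500))
  k27_mt <- intervals(rep("chr1", 2), c(1200, 49100), c(1700, 49400))
  atac_wt <- intervals("chr1", 10000, 10400)
  k27_wt <- intervals("chr1", 10100, 10300)
  cres <- genotype_specific_cres(atac_mt, k27_mt, atac_wt, k27_wt, genes,
                                 chrom_lengths = c(chr1 = 1e6))
  # peak 2 has no K27ac overlap in MT -> not a candidate at all
  expect_equal(nrow(cres), 2)
  # candidate at 49000 overlaps the promoter window [48000, 52000) -> kept
  # as a candidate but flagged non-distal
  expect_equal(cres$distal, c(TRUE, FALSE))
  expect_true(all(cres$specific))
  ds <- distal_specific(cres)
  expect_equal(nrow(ds), 1)
  expect_equal(ds$start, 1000)
  # a WT co-marked twin removes specificity of the matching candidate only
  atac_wt2 <- intervals(c("chr1", "chr1"), c(1000, 10000), c(1500, 10400))
  k27_wt2 <- intervals(c("chr1", "chr1"), c(1200, 10100), c(1700, 10300))
  cres2 <- genotype_specific_cres(atac_mt, k27_mt, atac_wt2, k27_wt2,
                                  genes, chrom_lengths = c(chr1 = 1e6))
  expect_equal(cres2$specific, c(FALSE, TRUE))
  # empty MT input warns and returns nothing
  expect_warning(
    out <- genotype_specific_cres(atac_mt[0, ], k27_mt, atac_wt, k27_wt,
                                  genes),
    "empty")
  expect_equal(nrow(out), 0)
})

test_that("specificity is order-independent", {
  set.seed(21)
  genes <- gene_models("g1", "chr1", "+", 900000, 910000)
  mk <- function(n, seed) rand_intervals(n, seed, chroms = "chr1",
                                         max_pos = 8e5)
  a_mt <- mk(40, 1); k_mt <- mk(40, 2); a_wt <- mk(40, 3); k_wt <- mk(40, 4)
  base <- genotype_specific_cres(a_mt, k_mt, a_wt, k_wt, genes)
  perm <- sample(nrow(a_mt))
  shuf <- genotype_specific_cres(a_mt[perm, ], k_mt, a_wt, k_wt, genes)
  key <- function(x) sort(paste(x$chrom, x$start, x$end, x$specific,
                                x$distal))
  expect_identical(key(base), key(shuf))
})

test_that("annotate_catalog fractions equal brute-force overlap counting", {
  cres <- rand_intervals(60, 31, chroms = "chr1")
  catalog <- rand_intervals(40, 32, chroms = "chr1")
  se <- rand_intervals(5, 33, chroms = "chr1")
  ann <- annotate_catalog(cres, catalog, se)
  want_ann <- nrow(unique(brute_overlap_pairs(cres, catalog)["query"])) /
    nrow(cres)
  want_se <- nrow(unique(brute_overlap_pairs(cres, se)["query"])) /
    nrow(cres)
  expect_equal(ann$frac_annotated, want_ann)
  expect_equal(ann$frac_super_enhancer, want_se)
  empty <- annotate_catalog(cres, NULL, NULL)
  expect_equal(empty$frac_annotated, 0)
})

test_that("pwm_scan: consensus, reverse complement, oracle agreement", {
  pwm <- ets_like_pwm()
  consensus <- paste(c("A", "C", "G", "T")[apply(pwm$matrix, 1,
                                                 which.max)],
                     collapse = "")
  expect_true(pwm_scan(consensus, pwm, score_frac = 1))
  rc <- paste(rev(chartr("ACGT", "TGCA",
                         strsplit(consensus, "")[[1]])), collapse = "")
  expect_true(pwm_scan(rc, pwm, score_frac = 1))
  # shorter than the motif -> no hit
  expect_false(pwm_scan("ACG", pwm))
  # random fixture equals the naive scanner
  set.seed(40)
  seqs <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = ""),
    character(1))
  got <- pwm_scan(seqs, pwm, score_frac = 0.8)
  want <- vapply(seqs, brute_pwm_hit, logical(1), pwm = pwm,
                 score_frac = 0.8, USE.NAMES = FALSE)
  expect_equal(as.logical(got), want)
})

test_that("JASPAR reader parses records into row-stochastic PWMs", {
  tmp <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TESTMOTIF",
               "A [ 10  2 90 ]",
               "C [ 10  2  2 ]",
               "G [ 70 94  4 ]",
               "T [ 10  2  4 ]"), tmp)
  pw <- read_jaspar(tmp)
  expect_named(pw, "MA0001.1")
  m <- pw[["MA0001.1"]]$matrix
  expect_equal(dim(m), c(3, 4))
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  expect_equal(unname(which.max(m[1, ])), 3)  # G dominates position 1
})

test_that("interval_enrichment: Fisher table, effect size, exact oracle", {
  set.seed(50)
  # construct fixed 2x2: a=30 b=70 c=10 d=90
  fg_hit <- intervals(rep("chr1", 30), seq(0, 29) * 1000,
                      seq(0, 29) * 1000 + 500)
  fg_miss <- intervals(rep("chr1", 70), 1e6 + seq(0, 69) * 1000,
                       1e6 + seq(0, 69) * 1000 + 500)
  bg_hit <- intervals(rep("chr1", 10), 2e6 + seq(0, 9) * 1000,
                      2e6 + seq(0, 9) * 1000 + 500)
  bg_miss <- intervals(rep("chr1", 90), 3e6 + seq(0, 89) * 1000,
                       3e6 + seq(0, 89) * 1000 + 500)
  fg <- rbind(fg_hit, fg_miss)
  bg <- rbind(bg_hit, bg_miss)
  catalog <- list(TF1 = rbind(fg_hit, bg_hit))
  res <- interval_enrichment(fg, bg, catalog)
  expect_equal(res$a, 30); expect_equal(res$c, 10)
  expect_equal(res$effect_size, 3.0)
  expect_equal(res$p, fisher_exact_brute(30, 70, 10, 90),
               tolerance = 1e-9)
  # doubling all counts keeps the effect size and reduces p
  fg2 <- rbind(fg, transform(fg, start = start + 5e6, end = end + 5e6))
  bg2 <- rbind(bg, transform(bg, start = start + 5e6, end = end + 5e6))
  catalog2 <- list(TF1 = rbind(catalog$TF1,
                               transform(catalog$TF1, start = start + 5e6,
                                         end = end + 5e6)))
  res2 <- interval_enrichment(fg2, bg2, catalog2)
  expect_equal(res2$effect_size, 3.0)
  expect_lt(res2$p, res$p)
  # overlapping background rejected
  expect_error(interval_enrichment(fg, fg, catalog),
               class = "epicmml_validation_error")
})

test_that("matched_background matches widths/chromosomes and avoids the foreground", {
  fg <- rand_intervals(25, 61, chroms = c("chr1", "chr2"), max_pos = 5e4)
  bg <- matched_background(fg, c(chr1 = 1e5, chr2 = 1e5), n_per = 2,
                           seed = 2)
  expect_equal(nrow(overlap_query(fg, bg)), 0)
  expect_setequal(unique(bg$end - bg$start), unique(fg$end - fg$start))
})
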