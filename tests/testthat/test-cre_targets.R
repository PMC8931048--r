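test_that("regulatory domains: basal orientation, lone gene, two-gene meeting", {
  # single gene: extension = TSS +/- cap (clipped)
  g1 <- gene_models("a", "chr1", "+", 2e6, 2.01e6)
  d1 <- regulatory_domains(g1, chrom_lengths = c(chr1 = 1e7))
  expect_equal(d1$basal_start, 2e6 - 5000)
  expect_equal(d1$basal_end, 2e6 + 1000)
  expect_equal(d1$ext_start, 2e6 - 1e6)
  expect_equal(d1$ext_end, 2e6 + 1e6)
  # minus strand basal is reflected: [tss - 1000, tss + 5000)
  gm <- gene_models("m", "chr1", "-", 1e6, 1.02e6)  # tss = 1.02e6 - 1
  dm <- regulatory_domains(gm, chrom_lengths = c(chr1 = 1e7))
  expect_equal(dm$basal_start, dm$tss - 1000)
  expect_equal(dm$basal_end, dm$tss + 5000)
  # two genes 100 kb apart: extensions meet at the neighbor's basal edge
  g2 <- gene_models(c("a", "b"), c("chr1", "chr1"), c("+", "+"),
                    c(1e6, 1.1e6), c(1.01e6, 1.11e6))
  d2 <- regulatory_domains(g2, chrom_lengths = c(chr1 = 1e7))
  expect_equal(d2$ext_end[1], d2$basal_start[2])   # a stops at b's basal
  expect_equal(d2$ext_start[2], d2$basal_end[1])   # b stops at a's basal
  # duplicate TSS warns, both kept
  gd <- gene_models(c("x", "y"), c("chr1", "chr1"), c("+", "+"),
                    c(1e6, 1e6), c(1.01e6, 1.02e6))
  expect_warning(dd <- regulatory_domains(gd), "duplicated TSS")
  expect_equal(nrow(dd), 2)
})

test_that("assign_targets: TAD filter, multi-assignment, distance bins", {
  genes <- gene_models(c("a", "b"), c("chr1", "chr1"), c("+", "+"),
                       c(100000, 140000), c(110000, 150000))
  doms <- regulatory_domains(genes, chrom_lengths = c(chr1 = 1e6))
  tads <- tad_set(intervals(c("chr1", "chr1"), c(0, 200000),
                            c(200000, 400000)))
  # CRE inside both extended domains and the same TAD -> two interactions
  cre <- intervals("chr1", 120000, 121000)
  out <- assign_targets(cre, doms, tads)
  expect_equal(sort(out$gene_id), c("a", "b"))
  expect_true(all(out$same_tad))
  expect_equal(out$distance[out$gene_id == "a"], abs(120500 - 100000))
  expect_equal(as.character(out$distance_bin[out$gene_id == "a"]),
               "5-50kb")
  # a CRE whose midpoint crosses into the next TAD is dropped
  genes2 <- gene_models("c", "chr1", "+", 190000, 195000)
  doms2 <- regulatory_domains(genes2, chrom_lengths = c(chr1 = 1e6))
  cre2 <- intervals("chr1", 210000, 211000)   # midpoint 210500, TAD 2
  out2 <- assign_targets(cre2, doms2, tads)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "n_dropped_tad"), 1L)
  # midpoint outside all TADs is dropped and counted
  cre3 <- intervals("chr1", 500000, 501000)
  out3 <- assign_targets(cre3, doms2, tads)
  expect_equal(attr(out3, "n_outside_tad"), 1L)
})

test_that("assign_targets equals the brute-force oracle on random fixtures", {
  brute_assign <- function(cres, doms, tads) {
    keys <- character(0)
    for (i in seq_len(nrow(cres))) {
      mid <- floor((cres$start[i] + cres$end[i]) / 2)
      for (j in seq_len(nrow(doms))) {
        if (cres$chrom[i] != doms$chrom[j]) next
        if (min(cres$end[i], doms$ext_end[j]) -
              max(cres$start[i], doms$ext_start[j]) < 1) next
        ct <- NA; tt <- NA
        for (k in seq_len(nrow(tads))) {
          if (tads$chrom[k] == cres$chrom[i] &&
                mid >= tads$start[k] && mid < tads$end[k]) ct <- k
          if (tads$chrom[k] == doms$chrom[j] &&
                doms$tss[j] >= tads$start[k] &&
                doms$tss[j] < tads$end[k]) tt <- k
        }
        if (!is.na(ct) && !is.na(tt) && ct == tt &&
              abs(mid - doms$tss[j]) <= 1e6)
          keys <- c(keys, paste(i, doms$gene_id[j]))
      }
    }
    sort(keys)
  }
  for (seed in 1:10) {
    set.seed(seed)
    n_genes <- 30
    tss <- sort(sample(seq(2e4, 9.8e5, by = 100), n_genes))
    genes <- gene_models(sprintf("g%02d", seq_len(n_genes)), "chr1",
                         sample(c("+", "-"), n_genes, TRUE),
                         tss, tss + sample(5e3:2e4, n_genes, TRUE))
    genes$tss <- tss   # fix tss independent of strand bookkeeping
    doms <- regulatory_domains(genes, chrom_lengths = c(chr1 = 1e6))
    tads <- tad_set(intervals("chr1", seq(0, 8e5, by = 2e5),
                              seq(2e5, 1e6, by = 2e5)))
    cres <- rand_intervals(50, seed + 99, chroms = "chr1",
                           max_pos = 9.9e5, max_width = 2000)
    got <- assign_targets(cres, doms, tads)
    expect_identical(sort(paste(got$cre_idx, got$gene_id)),
                     brute_assign(cres, doms, tads))
    expect_true(all(got$same_tad))
  }
})

test_that("overlap_significance is the exact hypergeometric upper tail", {
  # N=20, K=5, n=4, x=3 -> 155/4845
  expect_equal(overlap_significance(4, 5, 20, overlap = 3),
               155 / 4845, tolerance = 1e-12)
  # overlap 0 -> P(X >= 0) = 1
  expect_equal(overlap_significance(4, 5, 20, overlap = 0), 1)
  # monotone non-increasing in the observed overlap
  ps <- vapply(0:4, function(x) overlap_significance(4, 5, 20, overlap = x),
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  # set interface
  expect_equal(overlap_significance(c("a", "b", "c", "d"),
                                    c("a", "b", "e", "f", "g"), 20),
               overlap_significance(4, 5, 20, overlap = 2))
  expect_error(overlap_significance(4, 5, 20, overlap = 5),
               class = "epicmml_validation_error")
})

test_that("enhancer-expression association finds planted presence effects", {
  study <- small_study()
  cons_atac <- consensus_by_genotype(study, "ATAC")
  cons_k27 <- consensus_by_genotype(study, "H3K27ac")
  cres <- genotype_specific_cres(cons_atac$MT, cons_k27$MT,
                                 cons_atac$WT, cons_k27$WT, study$genes,
                                 chrom_lengths = study$layout$chrom_lengths)
  doms <- regulatory_domains(study$genes,
                             chrom_lengths = study$layout$chrom_lengths)
  inter <- assign_targets(distal_specific(cres), doms, study$tads)
  expect_gt(nrow(inter), 0)
  expect_true(all(inter$same_tad))
  # planted targets are recovered among the interaction genes
  expect_true(mean(study$truth$enhancer_targets %in% inter$gene_id) > 0.8)
  assoc <- enhancer_expression_association(inter, study$expression,
                                           study$samples,
                                           rownames(study$expression))
  expect_gt(assoc$presence$Z, 0)   # enhancers raise expression
  # empty interactions skip everything gracefully
  none <- enhancer_expression_association(inter[0, ], study$expression,
                                          study$samples,
                                          rownames(study$expression))
  expect_null(none$presence)
  expect_length(none$skipped, 3)
})
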