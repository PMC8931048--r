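# epicmml

Integrative epigenomic analysis of ASXL1-mutant chronic myelomonocytic
leukemia (CMML), re-implemented as a tested, reusable R pipeline.

Truncating *ASXL1* mutations define an aggressive CMML phenotype with
broadly up-regulated transcription. This package implements the analysis
chain that connects that transcriptional phenotype to chromatin: which
promoter chromatin states change between genotypes, whether gene-body
(hydroxy)methylation can explain the expression shift, whether
mutant-specific distal enhancers can, how the candidate mechanisms compare
in one multivariable model, and whether mutant chromatin is more
heterogeneous at single-cell resolution. It is aimed at computational
biologists who want each stage as a testable function rather than a
one-off script, and every stage runs end-to-end on a seeded synthetic
study with planted ground truth — no downloads.

## The methods at its core

* **Consensus peak calling** across replicates with the weak/stringent
  double threshold (p < 1e-4 / p < 1e-8): surviving peaks borrow strength
  from overlapping replicate peaks through Fisher's combined statistic,
  X² = −2 Σ ln p ~ χ²(2r), and confirmed peaks merge by union.
* **Chromatin states**: a K = 7 hidden Markov model with
  product-Bernoulli emissions over binarized H3K4me1 / H3K4me3 / H3K27ac /
  H3K27me3 / ATAC tracks (200 bp bins), Baum-Welch EM with restarts
  (compiled forward-backward/Viterbi), semantic state labels from an
  explicit emission rule, genotype contrast f_MT − f_WT over
  strand-oriented promoter windows (TSS ± 2000 bp), and occupancy dosage
  buckets.
* **Rank statistics** from first principles: Mann-Whitney U and Cuzick's
  trend test (midranks, tie-corrected variances, exact enumeration at
  small n, seeded permutation cross-checks), two-sample KS for single-cell
  entropy distributions.
* **Methylation**: gene-body coverage fractions, the dosage (5mC) vs
  threshold (5hmC) OLS model, and the isolated gene-body hypermethylation
  filter (hyper-DMR on the body, none on the promoter).
* **Enhancers**: MT-specific ATAC+H3K27ac co-marked distal elements,
  GREAT-style basal-plus-extension target assignment (5 kb/1 kb, 1 Mb cap)
  constrained to TADs, distance-bin structure, presence/dosage/distance
  association tests, hypergeometric overlap with up-regulated genes, PWM
  scanning and Fisher-exact catalog enrichment.
* **Integration**: ln(count + 1) OLS with e^β − 1 effects, the published
  leverage (h > 2k/n) and influence (Cook's D > 4/(n − k − 1)) exclusion
  rules, and exact LMG hierarchical R² partitioning.
* **Single-cell heterogeneity**: per-cell diversity entropy, feature
  specificity, and specialization (bits), compared between genotypes.

## Worked example

```r
library(epicmml)

study <- simulate_study(simulation_config(seed = 1))
study
#> simulated_study: 400 genes, 16 samples, 60 planted enhancers

ids <- function(g) study$samples$sample_id[study$samples$genotype == g]
cons <- lapply(c(WT = "WT", MT = "MT"), function(g)
  lapply(c(ATAC = "ATAC", H3K27ac = "H3K27ac"), function(m)
    combine_replicates(lapply(ids(g), function(s) study$peak_sets[[s]][[m]]))))

cres <- genotype_specific_cres(cons$MT$ATAC, cons$MT$H3K27ac,
                               cons$WT$ATAC, cons$WT$H3K27ac, study$genes,
                               chrom_lengths = study$layout$chrom_lengths)
ds <- distal_specific(cres)
nrow(ds)
#> [1] 60      # all 60 planted enhancers, nothing else

doms <- regulatory_domains(study$genes,
                           chrom_lengths = study$layout$chrom_lengths)
inter <- assign_targets(ds, doms, study$tads)
overlap_significance(unique(inter$gene_id), study$de_up,
                     nrow(study$expression))
#> [1] 2.68e-15   # enhancer targets are enriched for up-regulated genes
```

The 60 distal MT-specific elements produce 119 TAD-consistent
cis-interactions with 111 genes; 69 of those genes are in the 127-gene
up-regulated list, an overlap with hypergeometric p = 2.7e-15 — the toy
study's version of the enhancer-target/up-gene enrichment the method is
built to detect. The integration model on the same study (ground-truth
occupancy + methylation + assigned enhancers):

```r
fit <- fit_integration(X, y)   # X from integration_design(), y = MT median counts
fit
#> integration_fit: n = 400 (343 used), R2 = 0.9494
#>           term   beta effect     se     z        p
#> 1  (Intercept) 2.0138 6.4914 0.0240 83.84 0.00e+00
#> 2   active_occ 0.0195 0.0197 0.0003 66.75 0.00e+00
#> 3 inactive_occ 0.0010 0.0010 0.0009  1.03 3.04e-01
#> 4       mc_pct 0.0197 0.0199 0.0004 49.55 0.00e+00
#> 5  hmc_present 0.0071 0.0071 0.0224  0.32 7.52e-01
#> 6  enh_present 0.1728 0.1886 0.0262  6.59 4.47e-11
```

The planted per-percent effects (0.02 on active occupancy and methylation)
are recovered; `effect` is e^β − 1, so each percentage point of active
promoter occupancy raises expression by ~2 %. The enhancer presence effect
is positive and highly significant but attenuated from its planted 0.4
because multi-assignment includes neighbor genes (see the methods
vignette). Single-cell heterogeneity recovers the planted directions:

```r
het <- genotype_heterogeneity(study$sc)
#> diversity MT-WT: +1.31 bits (KS p < 1e-15)
#> specialization MT-WT: -1.57 bits (KS p < 1e-15)
```

A one-shot run of every stage, writing artifacts and seeded manifests:

```r
run_pipeline("all", pipeline_config(seed = 1), "epicmml_run")
```

## Documentation

The methods vignette (`vignettes/epicmml-methods.Rmd`) documents the
models and their assumptions, every tunable parameter with units and
defaults, what the synthetic world does and does not emulate, numerical
choices, and known limitations.
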