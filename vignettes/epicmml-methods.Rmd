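---
title: "Methods: integrative epigenomics of ASXL1-mutant CMML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative epigenomics of ASXL1-mutant CMML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`epicmml` re-implements, as a tested pipeline, an integrative epigenomic
analysis of chronic myelomonocytic leukemia (CMML) contrasting samples with
and without truncating *ASXL1* mutations (MT vs WT): chromatin-state
segmentation, genotype-specific distal enhancer discovery with
TAD-constrained target assignment, (hydroxy)methylation dosage models, a
multivariable model of expression with relative-importance decomposition,
and entropy-based single-cell heterogeneity statistics. This vignette
documents the models, the parameters that matter, the synthetic-data world
the tests run in, and the design decisions taken where the design was
genuinely open.

## Coordinate conventions

All intervals are 0-based half-open (BED convention) on unstranded
coordinates; GFF input is converted on read. Strand enters only when a TSS
is derived from a gene model (TSS = `start` on `+`, `end - 1` on `-`);
interval arithmetic never consults strand. Promoter windows are TSS ± 2000
bp, clipped at chromosome ends (whether the original analysis clipped is
not documented; clipping is the only choice that keeps windows valid).

## Consensus peak calling

Replicate peak sets are combined MSPC-style. Peaks with p ≥ 1e-4 (the
*weak* threshold) are discarded. Each surviving peak collects, from every
other replicate, its best (lowest-p) overlapping surviving peak, and the
evidence is combined with Fisher's statistic, X² = −2 Σ ln p on 2r degrees
of freedom. A peak is confirmed when the combined p beats the *stringent*
threshold 1e-8 with at least `ceiling(R/2)` contributing replicates
(majority rule; the replicate-support setting of the original analysis is
unstated), or when its own p is already below stringent. Mutually
overlapping confirmed peaks merge by union, carrying the smallest combined
p. Two open choices: one supporter per other replicate (the most stringent
overlapping peak) mirrors the cited consensus tool; union geometry
preserves all confirmed signal for downstream intersection. Broad marks
(H3K4me1, H2AK119ub, H3K27me3) differ only upstream; the consensus
arithmetic is identical.

## Chromatin states

Five binarized tracks (H3K4me1, H3K4me3, H3K27ac, H3K27me3, ATAC) in 200
bp bins feed a K-state hidden Markov model with product-Bernoulli
emissions. Binarization flags a bin when its count is improbable under a
Poisson background at the track's genome-wide mean rate
(P(X ≥ x) < 1e-4). The bin width is the segmentation convention of the
field's standard tool; the source analysis does not print one.

One model is learned by Baum-Welch EM on all samples concatenated
(chromosome boundaries break transitions), then decoded per sample —
states are subtracted between genotypes downstream, which presumes a
shared state vocabulary. EM runs with scaled forward-backward in compiled
code, 5 random restarts seeded from the master seed, convergence at
relative Δloglik < 1e-4, and emissions clamped to [1e-6, 1 − 1e-6]. The
log-likelihood is asserted non-decreasing in tests. K = 7 is the default,
the most parsimonious model that discriminates the six canonical state
classes; `select_states()` reports BIC and label coverage over K = 5..15,
breaking ties toward smaller K.

States get semantic labels from an explicit emission rule (threshold 0.5 =
"high"): active promoter = K4me3 ∧ K27ac; poised promoter = K4me3 ∧
K27me3; active enhancer = K4me1 ∧ K27ac ∧ ¬K4me3; inactive enhancer =
K4me1 alone; repressed = K27me3 alone; accessible-only = ATAC with all
histone marks low; quiescent = all low. The rule is a pure function of the
emission matrix, hence stable under state permutation and directly
testable. The original numeric state identities (01..07) cannot be
reproduced — no emission table is printed — so all downstream logic works
on labels.

Genotype contrast: per promoter position (strand-oriented, upstream left),
the consensus state per genotype is the modal state across that genotype's
samples (ties to the lowest state index; the original per-genotype
reduction is unstated), and `delta = f_MT − f_WT` sums to zero per
position by construction. Occupancy is the fraction of promoter bins per
state, averaged over samples, bucketed into 0, (0–25], (25–50], (50–75],
(75–100] percent (closed-right edges inferred from the figure banding).

## Rank-based association

`mann_whitney()` (presence vs absence) and `cuzick_trend()` (dosage across
occupancy buckets) are implemented from their formulas with midranks and
tie-corrected variances; both switch to exact enumeration for pooled sizes
≤ 12, and Cuzick exposes a seeded permutation cross-check. Expression is
summarized per gene as the within-genotype median of log(count + 1),
matching the nonparametric style of the analysis (the exact summary is not
printed); tests default to MT samples, as in the figures, with WT
available. P-values are reported raw, unadjusted, as in the figure
captions.

## Methylation

Gene-body (hydroxy)methylation *extent* is the fraction of body bp covered
by the union of consensus 5mC/5hmC peaks — the one summary reproducible
from interval inputs alone. The dosage-vs-threshold model is OLS of
log(count + 1) on `mc_fraction + hmc_present + hmc_fraction`: a dosage
pattern is a significant extent coefficient; a threshold pattern is a
significant presence coefficient without an extent effect (α = 0.05,
two-sided Wald). This four-term form is the minimal model expressing both
claimed patterns; the original model form is not printed. The isolated
gene-body hypermethylation filter flags up-regulated genes with a
significant hyper-DMR on the body and none on the promoter window. DMR
detection itself is out of scope; DMR tables are inputs.

## Enhancer discovery and targets

MT co-marked regions are ATAC consensus peaks overlapping an H3K27ac
consensus peak (element geometry = the ATAC peak: accessibility defines
the element, acetylation marks activity). MT-specific means zero bp
overlap with any WT co-marked region (strictest reading of "unique to";
`max_wt_overlap` exposes alternatives), and distal means no promoter
window overlap; the distal specific set feeds everything downstream.
Specificity against WT *co-marked* regions (not WT ATAC alone) was chosen
because the contrast of interest is active-enhancer state, not bare
accessibility.

Targets use GREAT-style basal-plus-extension domains (5 kb up / 1 kb down,
1 Mb cap — the cited tool's published defaults), multi-assignment allowed,
then the TAD filter: an interaction is kept only when the CRE midpoint and
the gene TSS share a TAD (midpoint resolves boundary-straddling regions).
Association tests: presence (Mann-Whitney), enhancer-count dosage (1 vs 2
vs ≥ 3, Cuzick), and distance trend over each gene's nearest enhancer
across the <5 kb / 5–50 kb / 50–200 kb / 200 kb–1 Mb bins. The gene-set
overlap against up-regulated genes uses the upper-tail hypergeometric; the
universe defaults to the expression matrix's gene count, since the
original universe behind the printed p-value is unstated — the procedure,
not that number, is reproducible.

Motif machinery scans JASPAR-format PWMs by log-odds against the
background on both strands (hit = best score ≥ 0.8 × the maximum
attainable; N contributes 0), replacing de novo discovery, which is out of
scope. Catalog enrichment uses Fisher's exact test on foreground vs
length- and chromosome-matched seeded random background regions, with fold
enrichment `(a/(a+b))/(c/(c+d))` as the effect size (the original effect
size is reported without definition).

## Integration model

`fit_integration()` fits ln(count + 1) by OLS on active occupancy
(percent; active promoter + active enhancer states), inactive occupancy
(poised + repressed), gene-body methylation (percent), hydroxymethylation
presence and enhancer presence. Percent scaling matches the "20% increase"
phrasing of the source; natural logs make `e^β − 1` the per-unit
multiplicative effect. One fit-exclude-refit pass removes observations
with leverage h > 2k/n or Cook's D > 4/(n − k − 1), k counting the model
covariates, exactly as stated; exclusion is not iterated. Note that with a
binary covariate the leverage rule is aggressive: rows with the rare level
are all excluded once the level count drops below roughly n/(k + 1) — a
real property of the published rule, and the reason the integration stage
needs covariates that are not too sparse at toy scale. LMG
relative-importance shares are computed by exact subset enumeration
(weights |S|!(k−|S|−1)!/k!) up to k = 10, with seeded ordering subsampling
beyond; shares sum to R² at machine tolerance. VIFs are reported but never
acted on.

## Single-cell heterogeneity

Per-cell profiles are normalized to p_fj. Diversity is per-cell Shannon
entropy (bits); feature specificity is
S_f = (1/T) Σ_j (p_fj/p̄_f) log2(p_fj/p̄_f); specialization is
δ_j = Σ_f p_fj S_f — the tissue-specificity information framework of the
entropy package the analysis cites, with cells as the framework's
"tissues". Genotypes are compared with the two-sample KS test (exact by
enumeration for pooled n ≤ 12, else the Kolmogorov asymptotic with
effective size n_x n_y/(n_x + n_y)). Motif accessibility ranking counts
peaks carrying each motif per genotype and ranks by the MT − WT
difference, on pooled-genotype peak sets (per-sample averaging available).

## The synthetic world

`simulate_study()` produces the study the tests run in: 2 chromosomes × 5
Mb in 200 bp bins, 400 genes, 8 + 8 samples, 60 planted enhancers, TADs
tiling in fixed 500 kb blocks (simple, and it guarantees the TAD filter is
exercised).

**Shared landscape.** One base state path is drawn per chromosome and
shared by all 16 samples; per-sample variation is Bernoulli emission
noise. This is deliberate: samples share a genome, and the genotype
subtraction can only remove background co-marked regions that replicate
across samples. Independent per-sample paths would make background regions
sample-private and planted-enhancer precision unattainable by
construction. Independent paths are used where parameter recovery is being
tested (`simulate_hmm_tracks()`).

**Planted contrasts.** Up-regulated genes (80) have promoters overridden
to poised or accessible-only in WT and active promoter in MT, mirroring
the loss-of-poised/gain-of-active transition; down-regulated genes (20)
the reverse. Planted enhancer loci are quiescent in WT and active-enhancer
in MT, which is exactly what produces MT-only ATAC + H3K27ac co-marking.
The true target of an enhancer is the nearest same-TAD gene to its
midpoint: with genes every ~25 kb, a gene chosen before placement would
usually not be the gene whose basal-plus-extension domain contains the
element, and end-to-end recovery would fail for geometric reasons, not
methodological ones.

**Peak p-values.** Peak strength grows with run length: 1-bin peaks are
weak (survive the weak threshold, cannot self-confirm), 2-bin peaks
stronger but still above stringent, runs ≥ 3 bins self-confirm. Short
peaks therefore need replicate support — the consensus stage is genuinely
exercised, and sample-private noise cannot leak through alone. Absent
marks emit at 0.02–0.05 and H3K27ac at 0.02 in non-acetylated states;
during development, mid-range absent-mark rates placed background regions
in the stochastic detection margin of the consensus caller, creating
genotype-asymmetric false co-marking — crisp high/low emissions are both
more realistic and what makes the subtraction well-posed.

**DE lists** are emitted from true effects: every gene with a nonzero
planted MT effect (promoter-override up genes plus enhancer targets) is
up-regulated; DE calling itself is out of scope.

**Expression.** counts = round(exp(β0 + βa·occ% + βm·meth% + βe·enh + ε) −
1), ε ~ N(0, 0.5), with βa = βm = 0.02 per percentage point and βe = 0.4 —
so the enhancer effect equals a 20-percentage-point increase in active
occupancy or methylation, the comparability the source states. The −1
mirrors the +1 pseudocount, so the log-linear fit recovers β without
transform bias. Log-normal noise (not negative-binomial) matches the scale
the integration model operates on; DE calling is out of scope and DE lists
are emitted from true effects.

**Methylation.** Genotype-independent (as observed in the source):
mc extent ~ 0 w.p. 0.3 else Beta(2,2); hmc presence ~ Bernoulli(0.5),
extent Beta(2,5). One spatially isolated up-regulated gene carries the
isolated body hyper-DMR; decoys include a body+promoter DMR, a hypo DMR
and a high-FDR DMR.

**Single cells.** WT cells are specialized: each draws a subtype and
concentrates 65% of its profile on that subtype's private feature group;
MT cells use the broad shared repertoire plus a thin layer over all
private groups, with a higher Dirichlet concentration (50 vs 5). This
yields MT cells with higher diversity and lower specialization — the
observed direction. A pure concentration contrast cannot produce it: lower
concentration lowers per-cell entropy (spikier draws), and per-cell
Dirichlet deviations are uncorrelated with pooled feature specificity, so
specialization barely moves. Specialization separates genotypes only when
specialized cells sit on globally specific features, which is also the
biological claim (differentiated WT subtypes vs broadly accessible MT
chromatin).

**What a green test does not establish.** The generator has no fragment- or
read-level noise, no GC or batch effects, no input-control structure, no
negative-binomial overdispersion, and TADs/genes on a regular grid; green
end-to-end tests establish that the algorithms recover what was planted
under the stated model, not performance on real sequencing data.

## Numerical choices

Emissions clamped to [1e-6, 1 − 1e-6]; forward-backward uses per-position
scaling (with a max-shift) rather than log-space sums; Viterbi runs in log
space; consensus p-values of exactly 0 are clamped to the smallest
positive double with a warning; modal-state ties break to the lowest state
index; occupancy buckets are closed on the right; PWM hits use a 1e-9
score tolerance to absorb summation-order rounding; OLS uses QR throughout
and LMG caches R² over the 2^k subsets.

## Known limitations

Multi-assignment of CREs to every overlapping regulatory domain means the
`enh_present` covariate in the integration stage includes neighbor genes
that carry no planted effect; at toy scale (genes every ~25 kb) roughly
half the assigned targets are such neighbors, so the fitted enhancer
effect is attenuated relative to the planted β — a property of the
assignment geometry, not an estimation error, and the reason the
parameter-recovery acceptance checks regress on true covariates while the
pipeline-level checks are directional. The CLI re-derives the simulated study from (config, seed) instead of
re-parsing every artifact — deterministic and cheap, but it means stage
subcommands only operate downstream of `simulate` runs, not on arbitrary
external inputs (the exported functions do). Config files are JSON, not
YAML (no YAML parser in the supported dependency set). Run-manifest
checksums are MD5 (base R); the determinism contract — same seed, same
checksums — is unaffected. The exact-enumeration branches of the rank and
KS tests are limited to pooled sizes ≤ 12; beyond that the tie-corrected
normal / Kolmogorov approximations apply.
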