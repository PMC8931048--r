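#' Default ground-truth chromatin-state model
#'
#' A 7-state product-Bernoulli HMM over the five canonical marks whose
#' emission rows realize the seven semantic labels (poised promoter,
#' repressed, inactive enhancer, accessible-only, active promoter, active
#' enhancer, quiescent). Transitions are sticky with a quiescent-heavy
#' stationary distribution, mimicking a mostly silent genome.
#'
#' @return `chrom_state_model` used as simulation ground truth.
#' @export
default_true_model <- function() {
  phi <- rbind(
    poised_promoter   = c(0.15, 0.90, 0.02, 0.85, 0.50),
    repressed         = c(0.05, 0.05, 0.02, 0.90, 0.02),
    inactive_enhancer = c(0.85, 0.05, 0.02, 0.05, 0.10),
    accessible        = c(0.05, 0.05, 0.02, 0.05, 0.90),
    active_promoter   = c(0.30, 0.90, 0.90, 0.05, 0.90),
    active_enhancer   = c(0.90, 0.10, 0.90, 0.05, 0.90),
    quiescent         = c(0.02, 0.02, 0.02, 0.02, 0.001))
  colnames(phi) <- hmm_marks
  K <- 7
  A <- matrix(0.01, K, K)
  diag(A) <- 0.80
  A[, K] <- A[, K] + 0.14          # everything decays toward quiescent
  A[K, ] <- c(rep(0.008, K - 1), 0)
  A[K, K] <- 1 - sum(A[K, -K])
  A <- A / rowSums(A)
  pi <- c(rep(0.03, K - 1), 1 - 0.03 * (K - 1))
  new_state_model(unname(phi), A, pi, NA_real_, hmm_marks)
}

#' Simulation configuration
#'
#' Defaults mirror the scale of the motivating study: two genotype groups
#' of 8 samples, a 2 x 5 Mb toy genome in 200 bp bins, 400 genes, 60
#' planted MT-specific distal enhancers, and a log-linear expression model
#' whose enhancer effect (`beta_enh` = 0.4) equals the effect of a
#' 20-percentage-point increase in active promoter occupancy or gene-body
#' methylation (`beta_active` = `beta_meth` = 0.02 per percent).
#'
#' @param seed master seed.
#' @param n_chrom,chrom_length,bin_width toy genome geometry.
#' @param n_genes total genes.
#' @param n_samples_per_genotype samples per genotype (default 8).
#' @param true_model ground-truth `chrom_state_model` (K = 7).
#' @param n_planted_enhancers MT-specific distal enhancers to plant.
#' @param n_up,n_down genes given genotype promoter-state overrides.
#' @param beta0,beta_active,beta_meth,beta_enh,sigma expression model:
#'   `count = round(exp(b0 + ba*occ_active + bm*mc_pct + be*enh + eps) - 1)`
#'   with occupancy/methylation in percent and `eps ~ N(0, sigma)`.
#' @param enhancer_width planted enhancer width in bp.
#' @param tad_width fixed TAD tiling width (default 500 kb).
#' @param cells_per_sample,n_features_sc,sc_depth single-cell matrix scale.
#' @param sc_groups number of WT subtype feature groups.
#' @param sc_private_frac fraction of features private to subtype groups.
#' @param sc_wt_private_weight profile mass a WT cell puts on its own
#'   private group (specialized, narrow repertoire).
#' @param sc_mt_private_weight thin profile mass MT cells spread over all
#'   private groups (broad repertoire).
#' @param dirichlet_conc named per-genotype Dirichlet concentrations for
#'   within-genotype profile noise; the MT concentration is higher so MT
#'   cells track the common broad profile. Together these make MT cells
#'   higher-diversity and lower-specialization, the direction the
#'   downstream entropy statistics must recover.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_chrom = 2, chrom_length = 5e6,
                              bin_width = 200, n_genes = 400,
                              n_samples_per_genotype = 8,
                              true_model = default_true_model(),
                              n_planted_enhancers = 60,
                              n_up = 80, n_down = 20,
                              beta0 = 2, beta_active = 0.02,
                              beta_meth = 0.02, beta_enh = 0.4,
                              sigma = 0.5, enhancer_width = 1000,
                              tad_width = 5e5, cells_per_sample = 300,
                              n_features_sc = 200, sc_depth = 2000,
                              sc_groups = 8, sc_private_frac = 0.5,
                              sc_wt_private_weight = 0.65,
                              sc_mt_private_weight = 0.1,
                              dirichlet_conc = c(WT = 5, MT = 50)) {
  cfg <- as.list(environment())
  counts <- c(n_chrom, chrom_length, bin_width, n_genes,
              n_samples_per_genotype, n_planted_enhancers, cells_per_sample,
              n_features_sc, sc_depth)
  if (any(counts <= 0) || sigma <= 0)
    abort_validation("all counts and sigma must be > 0")
  if (any(true_model$phi <= 0 | true_model$phi >= 1))
    abort_validation("true_model emissions must lie in (0,1)")
  class(cfg) <- "simulation_config"
  cfg
}

sample_markov_path <- function(K, A, pi, len) {
  path <- integer(len)
  cumA <- t(apply(A, 1, cumsum))
  u <- stats::runif(len)
  path[1] <- findInterval(u[1], cumsum(pi)) + 1L
  for (t in 2:len)
    path[t] <- findInterval(u[t], cumA[path[t - 1], ]) + 1L
  path
}

# runs of 1s in a 0/1 vector -> (start_bin, end_bin) 0-based bin coords
runs_of_ones <- function(v) {
  r <- rle(as.integer(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  cbind(start = starts[keep], end = ends[keep])
}

# peaks from one sample/mark binarized vector on one chromosome. P-value
# strength grows with run length: 1-bin peaks are weak (survive the weak
# threshold but cannot self-confirm), 2-bin peaks stronger but still below
# the stringent bar, runs >= 3 bins self-confirm. Short peaks therefore
# need replicate support -- the consensus stage is genuinely exercised and
# sample-private noise cannot leak through on its own.
peaks_from_bits <- function(bits, chrom, bw, chrom_len) {
  rr <- runs_of_ones(bits)
  if (!nrow(rr)) return(NULL)
  n <- nrow(rr)
  len <- rr[, "end"] - rr[, "start"]
  lo <- ifelse(len == 1, 4.5, ifelse(len == 2, 6.5, 9))
  hi <- ifelse(len == 1, 6, ifelse(len == 2, 8, 12))
  logp <- -stats::runif(n, lo, hi)
  data.frame(chrom = chrom, start = rr[, "start"] * bw,
             end = pmin(rr[, "end"] * bw, chrom_len),
             name = NA_character_, score = NA_real_, strand = "*",
             pvalue = 10^logp, stringsAsFactors = FALSE)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate a complete toy multi-omics study with planted ground truth
#'
#' One shared base chromatin-state path is drawn from the true model per
#' chromosome (the samples share a genome; per-sample variation enters as
#' Bernoulli emission noise). Genotype differences are planted on top:
#' up-regulated genes have their promoter bins overridden to poised or
#' accessible-only in WT and active promoter in MT; down-regulated genes
#' the reverse (active in WT, repressed in MT); planted enhancer loci are
#' quiescent in WT and active-enhancer in MT, which yields the MT-only
#' ATAC + H3K27ac co-marking the discovery stage must find. Expression
#' follows the log-linear model of the configuration; methylation is
#' genotype-independent; one designated up-regulated gene carries an
#' isolated gene-body hyper-DMR; single-cell profiles are Dirichlet draws
#' with genotype-specific concentration.
#'
#' @param cfg `simulation_config`.
#' @return list of class `simulated_study` with elements layout, genes,
#'   tads, samples, peak_sets (sample -> mark -> intervals), count_tracks,
#'   binarized (ground-truth presence), expression, de_up, de_down,
#'   mc_peaks, hmc_peaks, dmr_table, sc (cell_feature_matrix), truth.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  bw <- cfg$bin_width
  layout <- genome_layout(paste0("chr", seq_len(cfg$n_chrom)),
                          rep(cfg$chrom_length, cfg$n_chrom), bw)
  model <- cfg$true_model
  K <- model$K
  marks <- model$marks
  S <- 2 * cfg$n_samples_per_genotype
  samples <- data.frame(
    sample_id = c(paste0("WT", seq_len(cfg$n_samples_per_genotype)),
                  paste0("MT", seq_len(cfg$n_samples_per_genotype))),
    genotype = rep(c("WT", "MT"), each = cfg$n_samples_per_genotype),
    stringsAsFactors = FALSE)

  # TADs: fixed tiling
  tads <- do.call(rbind, lapply(layout$chrom_names, function(ch) {
    starts <- seq(0, cfg$chrom_length - 1, by = cfg$tad_width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + cfg$tad_width, cfg$chrom_length))
  }))
  tads <- tad_set(intervals(tads$chrom, tads$start, tads$end))

  # genes on a jittered grid, clear of chromosome ends
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  gl <- list()
  for (ch in layout$chrom_names) {
    n_here <- min(per_chrom, cfg$n_genes - length(gl))
    spacing <- (cfg$chrom_length - 1e5) / n_here
    tss <- round(5e4 + (seq_len(n_here) - 0.5) * spacing +
                   stats::runif(n_here, -spacing / 8, spacing / 8))
    strand <- sample(c("+", "-"), n_here, replace = TRUE)
    len <- round(stats::runif(n_here, 5e3, 2e4))
    start <- ifelse(strand == "+", tss, tss - len + 1)
    end <- start + len
    gl[[ch]] <- data.frame(chrom = ch, strand = strand, start = start,
                           end = end, stringsAsFactors = FALSE)
  }
  gdf <- do.call(rbind, gl)
  genes <- gene_models(sprintf("gene%03d", seq_len(nrow(gdf))), gdf$chrom,
                       gdf$strand, gdf$start, gdf$end)

  # designated gene sets
  reg_ids <- sample(genes$gene_id, cfg$n_up + cfg$n_down)
  up_genes <- reg_ids[seq_len(cfg$n_up)]
  down_genes <- reg_ids[cfg$n_up + seq_len(cfg$n_down)]
  up_wt_state <- sample(rep(c(1L, 4L), length.out = cfg$n_up)) # poised/accessible

  # shared base path per chromosome; genotype paths add planted overrides
  base_path <- integer(total_bins(layout))
  for (ch in layout$chrom_names) {
    idx <- layout$bin_offsets[ch] + seq_len(layout$n_bins[ch])
    base_path[idx] <- sample_markov_path(K, model$A, model$pi,
                                         layout$n_bins[ch])
  }
  state_of <- function(label) which(model$labels == label)[1]
  s_poised <- state_of("poised_promoter"); s_acc <- state_of("accessible")
  s_active <- state_of("active_promoter"); s_rep <- state_of("repressed")
  s_enh <- state_of("active_enhancer"); s_quiet <- state_of("quiescent")

  prom_bins <- promoter_bin_matrix(genes, layout, flank = 2000)
  path_wt <- base_path
  path_mt <- base_path
  for (i in seq_along(up_genes)) {
    b <- prom_bins[match(up_genes[i], genes$gene_id), ]
    path_wt[b] <- if (up_wt_state[i] == 1L) s_poised else s_acc
    path_mt[b] <- s_active
  }
  for (g in down_genes) {
    b <- prom_bins[match(g, genes$gene_id), ]
    path_wt[b] <- s_active
    path_mt[b] <- s_rep
  }

  # plant MT-specific distal enhancers: anchor near a sampled gene at
  # 5-200 kb, stay inside one TAD, clear of every promoter window. The
  # true target is the nearest gene (by TSS) in the enhancer's TAD -- the
  # gene the basal-plus-extension assignment will reach.
  n_enh <- cfg$n_planted_enhancers
  anchors <- sample(genes$gene_id, n_enh, replace = TRUE)
  prom_iv <- promoter_window(genes, 2000, layout$chrom_lengths)
  ewidth <- cfg$enhancer_width
  gene_tad <- locate_in_tads(genes$chrom, genes$tss, tads)
  enh_list <- list()
  targets <- character(n_enh)
  for (i in seq_len(n_enh)) {
    g <- genes[match(anchors[i], genes$gene_id), ]
    tad_i <- locate_in_tads(g$chrom, g$tss, tads)
    tlo <- tads$start[tad_i]; thi <- tads$end[tad_i]
    placed <- FALSE
    for (try in seq_len(400)) {
      d <- stats::runif(1, 5e3, 2e5) * sample(c(-1, 1), 1)
      mid_raw <- g$tss + d
      start <- floor((mid_raw - ewidth / 2) / bw) * bw
      end <- start + ewidth
      if (start < tlo || end > thi) next
      cand <- data.frame(chrom = g$chrom, start = start, end = end)
      if (nrow(overlap_query(cand, prom_iv))) next
      if (length(enh_list) &&
          nrow(overlap_query(cand, do.call(rbind, enh_list)))) next
      mid <- floor((start + end) / 2)
      in_tad <- which(genes$chrom == g$chrom & gene_tad == tad_i)
      dist <- abs(genes$tss[in_tad] - mid)
      nearest <- in_tad[which.min(dist)]
      if (min(dist) < 5e3 || min(dist) > 2e5) next
      enh_list[[i]] <- cand
      targets[i] <- genes$gene_id[nearest]
      placed <- TRUE
      break
    }
    if (!placed)
      abort_validation("cannot place enhancer in TAD of gene %s", anchors[i])
  }
  enh <- do.call(rbind, enh_list)
  planted <- intervals(enh$chrom, enh$start, enh$end, name = targets)

  # enhancer loci (plus a 2-bin margin) quiescent in WT, active enhancer
  # in MT; the margin keeps background peaks from abutting the element
  for (i in seq_len(nrow(planted))) {
    off <- layout$bin_offsets[planted$chrom[i]]
    b0 <- planted$start[i] / bw
    b1 <- planted$end[i] / bw
    core <- off + (b0 + 1):b1
    marg <- off + pmax(b0 - 1, 1):min(b1 + 2, layout$n_bins[planted$chrom[i]])
    path_wt[marg] <- s_quiet
    path_mt[marg] <- s_quiet
    path_mt[core] <- s_enh
  }

  # per-sample Bernoulli emissions, Poisson count tracks, peak sets
  B <- total_bins(layout)
  M <- length(marks)
  obs <- matrix(0L, S * B, M)
  counts <- matrix(0L, S * B, M)
  peak_sets <- vector("list", S)
  names(peak_sets) <- samples$sample_id
  lambda_bg <- 0.5; lambda_sig <- 30
  for (s in seq_len(S)) {
    path <- if (samples$genotype[s] == "WT") path_wt else path_mt
    prob <- model$phi[path, , drop = FALSE]
    o <- matrix(stats::rbinom(B * M, 1, as.numeric(prob)), B, M)
    rows <- (s - 1) * B + seq_len(B)
    obs[rows, ] <- o
    counts[rows, ] <- stats::rpois(B * M,
                                   ifelse(o == 1, lambda_sig, lambda_bg))
    pk <- list()
    for (m in seq_len(M)) {
      per_chrom_pk <- lapply(layout$chrom_names, function(ch) {
        idx <- layout$bin_offsets[ch] + seq_len(layout$n_bins[ch])
        peaks_from_bits(o[idx, m], ch, bw, layout$chrom_lengths[ch])
      })
      df <- do.call(rbind, per_chrom_pk)
      # weak decoys that the consensus stage must discard
      n_decoy <- 20
      dpos <- floor(stats::runif(n_decoy, 0, cfg$chrom_length - 5 * bw))
      decoys <- data.frame(chrom = sample(layout$chrom_names, n_decoy,
                                          replace = TRUE),
                           start = dpos, end = dpos + 2 * bw,
                           name = NA_character_, score = NA_real_,
                           strand = "*",
                           pvalue = 10^stats::runif(n_decoy, -3.9, -2),
                           stringsAsFactors = FALSE)
      df <- rbind(df, decoys)
      df <- sort_intervals(df)
      rownames(df) <- NULL
      class(df) <- c("intervals", "data.frame")
      pk[[marks[m]]] <- df
    }
    peak_sets[[s]] <- pk
  }

  # gene-body methylation, genotype-independent
  n_genes <- nrow(genes)
  mc_fraction <- ifelse(stats::runif(n_genes) < 0.3, 0,
                        stats::rbeta(n_genes, 2, 2))
  hmc_present <- stats::runif(n_genes) < 0.5
  hmc_fraction <- ifelse(hmc_present, stats::rbeta(n_genes, 2, 5), 0)
  meth_peaks <- function(frac) {
    keep <- which(frac > 0)
    if (!length(keep)) return(intervals(character(0), numeric(0), numeric(0)))
    g <- genes[keep, ]
    len <- (g$end - g$start) * frac[keep]
    offmax <- (g$end - g$start) - len
    off <- floor(stats::runif(length(keep)) * offmax)
    sort_intervals(intervals(g$chrom, g$start + off,
                             pmin(g$start + off + pmax(round(len), 1),
                                  g$end)))
  }
  mc_peaks <- meth_peaks(mc_fraction)
  hmc_peaks <- meth_peaks(hmc_fraction)

  # expression from the log-linear model on true covariates
  occ_active <- function(path) {
    vapply(seq_len(n_genes), function(i) {
      st <- path[prom_bins[i, ]]
      100 * mean(st %in% c(s_active, s_enh))
    }, numeric(1))
  }
  occ_wt <- occ_active(path_wt)
  occ_mt <- occ_active(path_mt)
  mc_pct <- 100 * mc_fraction
  enh_target <- genes$gene_id %in% targets
  expr <- matrix(0, n_genes, S,
                 dimnames = list(genes$gene_id, samples$sample_id))
  for (s in seq_len(S)) {
    mt <- samples$genotype[s] == "MT"
    mu <- cfg$beta0 + cfg$beta_active * (if (mt) occ_mt else occ_wt) +
      cfg$beta_meth * mc_pct +
      cfg$beta_enh * (if (mt) as.numeric(enh_target) else 0)
    expr[, s] <- pmax(round(exp(mu + stats::rnorm(n_genes, 0, cfg$sigma)) - 1),
                      0)
  }

  # DMRs: one isolated body hyper-DMR on a long-bodied up gene, plus decoys.
  # Candidate genes are spatially isolated (expanded span overlapping no
  # other gene) so a DMR on them cannot accidentally flag a neighbor.
  body_len <- genes$end - genes$start
  span <- intervals(genes$chrom, pmax(genes$start - 2500, 0),
                    genes$end + 2500, name = genes$gene_id)
  ov <- overlap_query(span, span)
  touched <- unique(ov$query[ov$query != ov$subject])
  isolated <- setdiff(genes$gene_id, genes$gene_id[touched])
  up_iso <- intersect(up_genes, isolated)
  if (length(up_iso) < 2)
    abort_validation("fewer than two isolated up-regulated genes; enlarge the genome")
  up_long <- up_iso[order(-body_len[match(up_iso, genes$gene_id)])]
  dmr_gene <- up_long[1]
  decoy_gene <- up_long[2]
  gi <- genes[match(dmr_gene, genes$gene_id), ]
  body_core <- c(max(gi$start, gi$tss - 2000) + 3000, gi$end)
  if (gi$strand == "-") body_core <- c(gi$start, min(gi$end, gi$tss - 3000))
  di <- genes[match(decoy_gene, genes$gene_id), ]
  other <- setdiff(genes$gene_id, reg_ids)[1]
  oi <- genes[match(other, genes$gene_id), ]
  dmrs <- dmr_table(data.frame(
    chrom = c(gi$chrom, di$chrom, di$chrom, oi$chrom, gi$chrom),
    start = c(body_core[1], di$start, di$tss - 500, oi$start, 10),
    end = c(body_core[1] + 1500, di$start + 1500, di$tss + 500,
            oi$start + 1500, 1200),
    direction = c("hyper", "hyper", "hyper", "hyper", "hypo"),
    area = c(1.61, 1.2, 0.9, 0.8, 1.0),
    fdr = c(0.018, 0.01, 0.02, 0.4, 0.01),
    stringsAsFactors = FALSE))

  # single-cell accessibility. WT cells are specialized: each belongs to a
  # subtype concentrating on a private feature group, so their profiles
  # are narrow (low diversity) and sit on globally specific features (high
  # specialization). MT cells draw on the broad shared repertoire plus a
  # thin layer over every private group: high diversity, low
  # specialization -- the direction the heterogeneity statistics must
  # recover. Dirichlet concentration adds within-genotype noise (tighter
  # for MT, which tracks the common profile).
  Fsc <- cfg$n_features_sc
  n_shared <- max(2, round(Fsc * (1 - cfg$sc_private_frac)))
  n_private <- Fsc - n_shared
  G <- min(cfg$sc_groups, n_private)
  group_of <- c(rep(0L, n_shared), rep(seq_len(G), length.out = n_private))
  base_shared <- numeric(Fsc)
  base_shared[group_of == 0L] <- rdirichlet1(rep(2, n_shared))
  unif_over <- function(sel) {
    v <- numeric(Fsc); v[sel] <- 1 / sum(sel); v
  }
  n_cells <- S * cfg$cells_per_sample
  cell_geno <- rep(samples$genotype, each = cfg$cells_per_sample)
  sc_counts <- matrix(0L, n_cells, Fsc,
                      dimnames = list(NULL, sprintf("TFM%03d", seq_len(Fsc))))
  m_mt <- (1 - cfg$sc_mt_private_weight) * base_shared +
    cfg$sc_mt_private_weight * unif_over(group_of > 0L)
  for (j in seq_len(n_cells)) {
    if (cell_geno[j] == "WT") {
      t <- sample.int(G, 1)
      m <- (1 - cfg$sc_wt_private_weight) * base_shared +
        cfg$sc_wt_private_weight * unif_over(group_of == t)
    } else {
      m <- m_mt
    }
    conc <- cfg$dirichlet_conc[[cell_geno[j]]]
    pj <- rdirichlet1(conc * Fsc * m)
    sc_counts[j, ] <- stats::rmultinom(1, cfg$sc_depth, pj)
  }
  sc <- cell_feature_matrix(sc_counts, cell_geno,
                            sprintf("cell%05d", seq_len(n_cells)))

  truth <- list(
    base_path = base_path, path_wt = path_wt, path_mt = path_mt,
    planted_enhancers = planted, enhancer_targets = targets,
    true_betas = c(beta0 = cfg$beta0, beta_active = cfg$beta_active,
                   beta_meth = cfg$beta_meth, beta_enh = cfg$beta_enh),
    sigma = cfg$sigma,
    occ_active = cbind(WT = occ_wt, MT = occ_mt),
    mc_fraction = mc_fraction, hmc_present = hmc_present,
    hmc_fraction = hmc_fraction,
    dmr_gene = dmr_gene, up_genes = up_genes, down_genes = down_genes,
    up_wt_state = up_wt_state)

  # DE lists carry every gene with a nonzero planted MT effect: the
  # promoter-override up genes and the enhancer target genes
  de_up <- union(up_genes, targets)
  structure(list(config = cfg, layout = layout, genes = genes, tads = tads,
                 samples = samples, peak_sets = peak_sets,
                 count_tracks = counts, binarized = obs, marks = marks,
                 expression = expr, de_up = de_up, de_down = down_genes,
                 mc_peaks = mc_peaks, hmc_peaks = hmc_peaks,
                 dmr_table = dmrs, sc = sc, truth = truth),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("simulated_study:", nrow(x$genes), "genes,", nrow(x$samples),
      "samples,", nrow(x$truth$planted_enhancers), "planted enhancers\n")
  invisible(x)
}

#' Simulate replicate peak sets around one true region
#'
#' Replicate peaks are jittered around `true_region` with strong p-values
#' (log-uniform in [1e-12, 1e-3]); `n_decoys` decoy peaks with p-values at
#' or above the weak threshold are added per replicate.
#'
#' @param n_replicates number of replicates (>= 1).
#' @param true_region single-row interval table.
#' @param noise maximal absolute jitter of each edge in bp (0 = exact).
#' @param n_decoys decoys per replicate (default 3).
#' @param weak weak threshold decoys must not beat (default 1e-4).
#' @param seed RNG seed.
#' @return list of per-replicate interval tables with `pvalue`.
#' @export
simulate_peak_pvalues <- function(n_replicates, true_region, noise = 0,
                                  n_decoys = 3, weak = 1e-4, seed = 1) {
  if (n_replicates < 1) abort_validation("n_replicates must be >= 1")
  set.seed(seed)
  lapply(seq_len(n_replicates), function(r) {
    j1 <- if (noise > 0) round(stats::runif(1, -noise, noise)) else 0
    j2 <- if (noise > 0) round(stats::runif(1, -noise, noise)) else 0
    start <- max(0, true_region$start + j1)
    end <- max(start + 1, true_region$end + j2)
    dstart <- true_region$end + 1e4 * seq_len(n_decoys)
    df <- data.frame(
      chrom = c(true_region$chrom, rep(true_region$chrom, n_decoys)),
      start = c(start, dstart), end = c(end, dstart + 500),
      name = NA_character_, score = NA_real_, strand = "*",
      pvalue = c(10^stats::runif(1, -12, -3.01),
                 10^stats::runif(n_decoys, log10(weak), -2)),
      stringsAsFactors = FALSE)
    df <- sort_intervals(df)
    class(df) <- c("intervals", "data.frame")
    df
  })
}

#' Simulate binarized tracks from a chromatin-state model
#'
#' Unlike [simulate_study()], every sample gets its own independent state
#' path -- the fixture for HMM parameter-recovery checks.
#'
#' @param model `chrom_state_model`.
#' @param n_samples samples to draw.
#' @param n_bins bins per sample (one chromosome).
#' @param seed RNG seed.
#' @param bin_width bin width bp.
#' @return list with `tracks` (`binarized_tracks`) and `paths`
#'   (sample x bin true states).
#' @export
simulate_hmm_tracks <- function(model, n_samples, n_bins, seed = 1,
                                bin_width = 200) {
  set.seed(seed)
  layout <- genome_layout("chr1", n_bins * bin_width, bin_width)
  K <- model$K
  M <- length(model$marks)
  paths <- matrix(0L, n_samples, n_bins)
  obs <- matrix(0L, n_samples * n_bins, M)
  for (s in seq_len(n_samples)) {
    p <- sample_markov_path(K, model$A, model$pi, n_bins)
    paths[s, ] <- p
    prob <- model$phi[p, , drop = FALSE]
    obs[(s - 1) * n_bins + seq_len(n_bins), ] <-
      stats::rbinom(n_bins * M, 1, as.numeric(prob))
  }
  samples <- data.frame(sample_id = paste0("sim", seq_len(n_samples)),
                        genotype = rep(c("WT", "MT"),
                                       length.out = n_samples),
                        stringsAsFactors = FALSE)
  list(tracks = binarized_tracks(obs, samples, model$marks, layout),
       paths = paths)
}

#' Simulate expression from a design under the log-linear model
#'
#' `count = pmax(round(exp(X beta + eps) - 1), 0)`, `eps ~ N(0, sigma)`.
#' Shared by the parameter-recovery tests.
#'
#' @param design n x k covariate matrix.
#' @param beta0 intercept.
#' @param betas covariate coefficients (length k).
#' @param sigma noise SD.
#' @param seed RNG seed.
#' @return integer count vector.
#' @export
simulate_expression <- function(design, beta0, betas, sigma, seed = 1) {
  set.seed(seed)
  mu <- beta0 + as.matrix(design) %*% betas
  pmax(round(exp(mu + stats::rnorm(nrow(design), 0, sigma)) - 1), 0)
}
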