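#' Basal-plus-extension regulatory domains
#'
#' Each gene gets a strand-oriented basal domain (`basal_up` bp upstream to
#' `basal_down` bp downstream of the TSS) extended in both directions to
#' the nearest neighboring gene's basal domain edge, capped at `cap` bp
#' from the TSS. Extended domains may overlap; extension never shrinks a
#' basal domain.
#'
#' @param genes gene-model table (any order; sorted internally).
#' @param basal_up,basal_down basal extent upstream/downstream of the TSS
#'   (defaults 5000 / 1000 bp).
#' @param cap maximum extension distance from the TSS (default 1e6 bp).
#' @param chrom_lengths optional named lengths for clipping.
#' @return data.frame of class `regulatory_domains`: gene_id, chrom, tss,
#'   basal_start, basal_end, ext_start, ext_end.
#' @export
regulatory_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                               cap = 1e6, chrom_lengths = NULL) {
  up <- ifelse(genes$strand == "+", basal_up, basal_down)
  down <- ifelse(genes$strand == "+", basal_down, basal_up)
  basal_start <- pmax(genes$tss - up, 0)
  basal_end <- genes$tss + down
  if (!is.null(chrom_lengths))
    basal_end <- pmin(basal_end, chrom_lengths[genes$chrom])
  dup <- duplicated(paste(genes$chrom, genes$tss))
  if (any(dup)) warning(sprintf("%d duplicated TSS; all genes kept", sum(dup)))
  n <- nrow(genes)
  ext_start <- pmax(genes$tss - cap, 0)
  ext_end <- genes$tss + cap
  if (!is.null(chrom_lengths))
    ext_end <- pmin(ext_end, chrom_lengths[genes$chrom])
  for (chrom in unique(genes$chrom)) {
    idx <- which(genes$chrom == chrom)
    for (i in idx) {
      others <- setdiff(idx, i)
      if (!length(others)) next
      # nearest basal edge on each side, never shrinking own basal
      left_edges <- basal_end[others][basal_end[others] <= basal_start[i]]
      if (length(left_edges))
        ext_start[i] <- max(ext_start[i], max(left_edges))
      right_edges <- basal_start[others][basal_start[others] >= basal_end[i]]
      if (length(right_edges))
        ext_end[i] <- min(ext_end[i], min(right_edges))
      # a neighbor basal overlapping ours leaves no room to extend
      if (any(basal_end[others] > basal_start[i] &
                basal_start[others] < basal_start[i]))
        ext_start[i] <- basal_start[i]
      if (any(basal_start[others] < basal_end[i] &
                basal_end[others] > basal_end[i]))
        ext_end[i] <- basal_end[i]
    }
  }
  ext_start <- pmin(ext_start, basal_start)
  ext_end <- pmax(ext_end, basal_end)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    tss = genes$tss, basal_start = basal_start,
                    basal_end = basal_end, ext_start = ext_start,
                    ext_end = ext_end, stringsAsFactors = FALSE)
  class(out) <- c("regulatory_domains", "data.frame")
  out
}

distance_bin <- function(d) {
  cut(d, breaks = c(-Inf, 5e3, 5e4, 2e5, 1e6),
      labels = c("<5kb", "5-50kb", "50-200kb", "200kb-1Mb"))
}

#' Assign distal CREs to putative target genes
#'
#' A CRE is associated with every gene whose extended regulatory domain it
#' overlaps (multi-assignment allowed). An association is retained only
#' when the CRE midpoint and the gene TSS fall inside the same TAD;
#' midpoints outside all TADs are dropped and counted.
#'
#' @param cres interval table of distal MT-specific CREs.
#' @param domains `regulatory_domains`.
#' @param tads `tad_set`.
#' @return data.frame of class `cis_interactions`: cre_idx, chrom,
#'   cre_start, cre_end, gene_id, tss, distance, distance_bin, same_tad
#'   (all TRUE by construction). Attribute `n_dropped_tad` counts
#'   cross-TAD losses, `n_outside_tad` midpoints outside all TADs.
#' @export
assign_targets <- function(cres, domains, tads) {
  dom_iv <- intervals(domains$chrom, domains$ext_start, domains$ext_end,
                      name = domains$gene_id)
  hits <- overlap_query(cres, dom_iv)
  empty <- {
    z <- data.frame(cre_idx = integer(0), chrom = character(0),
                    cre_start = numeric(0), cre_end = numeric(0),
                    gene_id = character(0), tss = numeric(0),
                    distance = numeric(0),
                    distance_bin = distance_bin(numeric(0)),
                    same_tad = logical(0))
    class(z) <- c("cis_interactions", "data.frame"); z
  }
  if (!nrow(hits)) {
    attr(empty, "n_dropped_tad") <- 0L
    attr(empty, "n_outside_tad") <- 0L
    return(empty)
  }
  mid <- floor((cres$start + cres$end) / 2)
  cre_tad <- locate_in_tads(cres$chrom, mid, tads)
  tss_tad <- locate_in_tads(domains$chrom, domains$tss, tads)
  ct <- cre_tad[hits$query]
  tt <- tss_tad[hits$subject]
  outside <- is.na(ct)
  same <- !outside & !is.na(tt) & ct == tt
  out <- data.frame(cre_idx = hits$query[same],
                    chrom = cres$chrom[hits$query[same]],
                    cre_start = cres$start[hits$query[same]],
                    cre_end = cres$end[hits$query[same]],
                    gene_id = domains$gene_id[hits$subject[same]],
                    tss = domains$tss[hits$subject[same]],
                    stringsAsFactors = FALSE)
  out$distance <- abs(mid[hits$query[same]] - out$tss)
  keep <- out$distance <= 1e6
  out <- out[keep, , drop = FALSE]
  out$distance_bin <- distance_bin(out$distance)
  out$same_tad <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  attr(out, "n_dropped_tad") <- sum(!same & !outside)
  attr(out, "n_outside_tad") <- sum(outside)
  class(out) <- c("cis_interactions", "data.frame")
  out
}

#' Enhancer-expression association tests
#'
#' Three tests over the gene universe: (1) presence of >= 1 retained
#' cis-interaction vs none (Mann-Whitney on expression); (2) enhancer count
#' dosage (1 vs 2 vs >= 3 enhancers, Cuzick trend, among target genes);
#' (3) distance trend across the nearest-enhancer distance bins (Cuzick).
#' Expression is the within-genotype median of log(count + 1).
#'
#' @param interactions `cis_interactions`.
#' @param expr gene x sample count matrix.
#' @param samples sample data.frame.
#' @param universe gene ids forming the testing universe.
#' @param genotype expression summary genotype (default "MT").
#' @return list with `presence`, `count_dosage`, `distance_trend`
#'   (NULL when skipped, with `skipped` naming the reasons).
#' @export
enhancer_expression_association <- function(interactions, expr, samples,
                                            universe, genotype = "MT") {
  universe <- intersect(universe, rownames(expr))
  e <- summarize_expression(expr[universe, , drop = FALSE], samples,
                            genotype)
  skipped <- character(0)
  if (nrow(interactions) == 0) {
    return(list(presence = NULL, count_dosage = NULL, distance_trend = NULL,
                skipped = c("presence", "count_dosage", "distance_trend")))
  }
  cnt <- table(interactions$gene_id)
  n_enh <- stats::setNames(rep(0L, length(universe)), universe)
  common <- intersect(names(cnt), universe)
  n_enh[common] <- as.integer(cnt[common])
  has <- n_enh > 0
  presence <- if (any(has) && any(!has)) mann_whitney(e[has], e[!has])
              else { skipped <- c(skipped, "presence"); NULL }
  # dosage among target genes: 1 vs 2 vs >= 3
  dosage_groups <- list(e[n_enh == 1], e[n_enh == 2], e[n_enh >= 3])
  count_dosage <- if (sum(lengths(dosage_groups) > 0) >= 2)
    cuzick_trend(dosage_groups[lengths(dosage_groups) > 0],
                 scores = which(lengths(dosage_groups) > 0))
  else { skipped <- c(skipped, "count_dosage"); NULL }
  # distance trend: nearest enhancer per target gene
  nearest <- tapply(interactions$distance, interactions$gene_id, min)
  nearest <- nearest[intersect(names(nearest), universe)]
  db <- distance_bin(as.numeric(nearest))
  dg <- split(e[names(nearest)], db)
  distance_trend <- if (sum(lengths(dg) > 0) >= 2)
    cuzick_trend(dg[lengths(dg) > 0], scores = which(lengths(dg) > 0))
  else { skipped <- c(skipped, "distance_trend"); NULL }
  list(presence = presence, count_dosage = count_dosage,
       distance_trend = distance_trend, skipped = skipped)
}

#' Hypergeometric significance of a gene-set overlap
#'
#' Upper-tail probability `P(X >= overlap)` of drawing at least the
#' observed overlap when `n_targets` genes are drawn without replacement
#' from a universe containing `n_de_up` successes.
#'
#' @param targets target gene ids (or a count).
#' @param de_up up-regulated gene ids (or a count).
#' @param universe_size population size.
#' @param overlap observed overlap; computed from the sets when both are
#'   character vectors.
#' @return upper-tail hypergeometric p-value.
#' @export
overlap_significance <- function(targets, de_up, universe_size,
                                 overlap = NULL) {
  n_t <- if (is.character(targets)) length(unique(targets)) else targets
  n_d <- if (is.character(de_up)) length(unique(de_up)) else de_up
  if (is.null(overlap)) {
    if (!is.character(targets) || !is.character(de_up))
      abort_validation("overlap must be given when sets are counts")
    overlap <- length(intersect(unique(targets), unique(de_up)))
  }
  if (n_t > universe_size || n_d > universe_size)
    abort_validation("set larger than the universe")
  if (overlap > min(n_t, n_d))
    abort_validation("overlap exceeds the smaller set")
  stats::phyper(overlap - 1, n_d, universe_size - n_d, n_t,
                lower.tail = FALSE)
}

#' Write cis-interactions as BEDPE-like TSV
#' @param interactions `cis_interactions`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  utils::write.table(
    interactions[, c("chrom", "cre_start", "cre_end", "gene_id", "tss",
                     "distance", "distance_bin", "same_tad")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
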