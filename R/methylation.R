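#' Gene-body (hydroxy)methylation extent
#'
#' Extent is the fraction of gene-body bp covered by the union of consensus
#' 5mC (or 5hmC) peaks; presence is any coverage at all. Extents are also
#' bucketed like promoter occupancy (0, (0-25], ..., (75-100] percent).
#'
#' @param mc_peaks consensus 5mC interval table.
#' @param hmc_peaks consensus 5hmC interval table.
#' @param genes gene-model table.
#' @return data.frame of class `methylation_summary`: gene_id, mc_fraction,
#'   hmc_fraction, mc_bucket, hmc_bucket, mc_present, hmc_present.
#' @export
gene_body_fraction <- function(mc_peaks, hmc_peaks, genes) {
  if (any(genes$end <= genes$start))
    abort_validation("zero-length gene body")
  bodies <- intervals(genes$chrom, genes$start, genes$end,
                      name = genes$gene_id)
  cover <- function(peaks) {
    if (is.null(peaks) || nrow(peaks) == 0) return(numeric(nrow(genes)))
    peaks <- reduce_intervals(peaks)  # union first; overlaps then disjoint
    hits <- overlap_query(bodies, peaks, min_bp = 1)
    cov <- numeric(nrow(genes))
    if (nrow(hits)) {
      w <- overlap_widths(bodies, peaks, hits)
      agg <- tapply(w, hits$query, sum)
      cov[as.integer(names(agg))] <- as.numeric(agg)
    }
    cov / (genes$end - genes$start)
  }
  mc <- cover(mc_peaks)
  hmc <- cover(hmc_peaks)
  out <- data.frame(gene_id = genes$gene_id,
                    mc_fraction = mc, hmc_fraction = hmc,
                    mc_bucket = occupancy_bucket(mc),
                    hmc_bucket = occupancy_bucket(hmc),
                    mc_present = mc > 0, hmc_present = hmc > 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("methylation_summary", "data.frame")
  out
}

#' Dosage-vs-threshold methylation model of expression
#'
#' Ordinary least squares of `log(count + 1)` on methylation extent,
#' hydroxymethylation presence and hydroxymethylation extent:
#' \deqn{y = b0 + b1 mc\_fraction + b2 hmc\_present + b3 hmc\_fraction}
#' The *threshold* pattern for hydroxymethylation is declared when the
#' presence coefficient (b2) rejects and the extent coefficient (b3) does
#' not, at `alpha`; a *dosage* pattern for methylation when b1 rejects.
#'
#' @param summary `methylation_summary`.
#' @param expr gene x sample count matrix.
#' @param samples sample data.frame.
#' @param genotype expression summary genotype (default "MT").
#' @param alpha test level for the pattern calls (default 0.05).
#' @return list with `coefficients` data.frame (term, beta, se, z, p),
#'   `threshold_pattern`, `dosage_pattern`, `n`.
#' @export
meth_expression_model <- function(summary, expr, samples, genotype = "MT",
                                  alpha = 0.05) {
  genes <- intersect(summary$gene_id, rownames(expr))
  if (length(genes) < 10)
    abort_validation("need >= 10 genes shared between summary and expression")
  s <- summary[match(genes, summary$gene_id), ]
  X <- cbind(mc_fraction = s$mc_fraction,
             hmc_present = as.numeric(s$hmc_present),
             hmc_fraction = s$hmc_fraction)
  novar <- apply(X, 2, stats::sd) == 0
  if (all(novar)) abort_validation("all covariates have zero variance")
  y <- summarize_expression(expr[genes, , drop = FALSE], samples, genotype)
  Xd <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) {
    # name a dependent pair for the error message
    cn <- colnames(Xd)
    abort_validation("collinear covariates (rank %d < %d): check %s",
                     qx$rank, ncol(Xd),
                     paste(cn[qx$pivot[(qx$rank + 1):ncol(Xd)]],
                           collapse = ", "))
  }
  kappa_x <- kappa(Xd, exact = TRUE)
  if (kappa_x > 1e8)
    abort_numeric("design condition number %.3g > 1e8", kappa_x)
  fit <- stats::lm.fit(Xd, y)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- length(y) - ncol(Xd)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(XtXinv) * s2)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  co <- data.frame(term = names(beta), beta = as.numeric(beta), se = se,
                   z = as.numeric(z), p = as.numeric(p),
                   stringsAsFactors = FALSE, row.names = NULL)
  list(coefficients = co,
       threshold_pattern = co$p[co$term == "hmc_present"] < alpha &&
         co$p[co$term == "hmc_fraction"] >= alpha,
       dosage_pattern = co$p[co$term == "mc_fraction"] < alpha,
       n = length(y))
}

#' Read a DMR table
#'
#' Tab-separated columns: chrom, start, end, direction (hyper/hypo), area,
#' fdr (header optional, detected).
#'
#' @param path TSV path.
#' @return data.frame of class `dmr_table`.
#' @export
read_dmrs <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("chrom", first, fixed = TRUE)
  x <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end", "direction", "area", "fdr")
  dmr_table(x)
}

#' Validate a DMR table
#' @param x data.frame with chrom, start, end, direction, area, fdr.
#' @return `x` with class `dmr_table`.
#' @export
dmr_table <- function(x) {
  validate_intervals(x)
  if (!all(x$direction %in% c("hyper", "hypo")))
    abort_validation("DMR direction must be 'hyper' or 'hypo'")
  if (any(x$fdr < 0 | x$fdr > 1)) abort_validation("DMR fdr outside [0,1]")
  class(x) <- c("dmr_table", "data.frame")
  x
}

#' Isolated gene-body hypermethylation filter
#'
#' Flags up-regulated genes whose body overlaps a significant
#' hypermethylated DMR while their promoter window overlaps none: the
#' "isolated gene body hypermethylation" pattern.
#'
#' @param dmrs `dmr_table`.
#' @param genes gene-model table.
#' @param de_up up-regulated gene ids.
#' @param fdr_cut DMR significance cut (default 0.05).
#' @param flank promoter half-width (default 2000).
#' @param chrom_lengths optional lengths for promoter clipping.
#' @return character vector of flagged gene ids.
#' @export
isolated_hypermethylation_filter <- function(dmrs, genes, de_up,
                                             fdr_cut = 0.05, flank = 2000,
                                             chrom_lengths = NULL) {
  sig <- dmrs[dmrs$direction == "hyper" & dmrs$fdr < fdr_cut, , drop = FALSE]
  if (nrow(sig) == 0) return(character(0))
  bodies <- intervals(genes$chrom, genes$start, genes$end)
  prom <- promoter_window(genes, flank, chrom_lengths)
  body_hit <- unique(overlap_query(bodies, sig)$query)
  prom_hit <- unique(overlap_query(prom, sig)$query)
  idx <- setdiff(body_hit, prom_hit)
  intersect(genes$gene_id[idx], de_up)
}
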