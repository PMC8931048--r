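#' Build a cell x feature accessibility matrix
#'
#' All-zero cells are dropped on load with the count reported.
#'
#' @param counts cell x feature nonnegative matrix (dense or sparse).
#' @param genotype genotype label per cell ("WT"/"MT").
#' @param cell_id optional cell identifiers.
#' @return object of class `cell_feature_matrix`.
#' @export
cell_feature_matrix <- function(counts, genotype, cell_id = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort_validation("negative accessibility counts")
  if (length(genotype) != nrow(counts))
    abort_validation("one genotype label per cell required")
  if (is.null(cell_id)) cell_id <- paste0("cell", seq_len(nrow(counts)))
  keep <- rowSums(counts) > 0
  if (any(!keep))
    message(sprintf("dropped %d all-zero cell(s)", sum(!keep)))
  structure(list(counts = counts[keep, , drop = FALSE],
                 genotype = genotype[keep], cell_id = cell_id[keep],
                 n_dropped = sum(!keep)),
            class = "cell_feature_matrix")
}

#' Entropy-based diversity, specificity and specialization
#'
#' Per-cell profiles are normalized to \eqn{p_{fj}}. Diversity is the
#' per-cell Shannon entropy \eqn{H_j = -\sum_f p_{fj} \log_2 p_{fj}}
#' (with 0 log 0 = 0). Feature specificity is
#' \eqn{S_f = (1/T) \sum_j (p_{fj}/\bar p_f) \log_2 (p_{fj}/\bar p_f)}
#' over the T cells, with \eqn{\bar p_f} the across-cell mean profile;
#' features with \eqn{\bar p_f = 0} are excluded with a warning. Per-cell
#' specialization is \eqn{\delta_j = \sum_f p_{fj} S_f}. All quantities in
#' bits.
#'
#' @param m `cell_feature_matrix` (>= 2 features).
#' @return list of class `entropy_profile`: `diversity` (per cell),
#'   `specificity` (per feature), `specialization` (per cell), `genotype`.
#' @export
entropy_profiles <- function(m) {
  counts <- m$counts
  if (ncol(counts) < 2) abort_validation("need >= 2 features")
  p <- counts / rowSums(counts)
  plog <- p * log2(p)
  plog[p == 0] <- 0
  H <- -rowSums(plog)
  pbar <- colMeans(p)
  zero <- pbar == 0
  if (any(zero))
    warning(sprintf("%d feature(s) with zero mean excluded from specificity",
                    sum(zero)))
  ratio <- sweep(p[, !zero, drop = FALSE], 2, pbar[!zero], "/")
  rlog <- ratio * log2(ratio)
  rlog[ratio == 0] <- 0
  S <- colMeans(rlog)
  delta <- as.numeric(p[, !zero, drop = FALSE] %*% S)
  structure(list(diversity = stats::setNames(H, m$cell_id),
                 specificity = S,
                 specialization = stats::setNames(delta, m$cell_id),
                 genotype = m$genotype),
            class = "entropy_profile")
}

# Kolmogorov asymptotic survival function Q(lambda) = 2 sum (-1)^{k-1} e^{-2k^2 lambda^2}
kolmogorov_q <- function(lambda) {
  if (lambda < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs. The
#' p-value is exact by enumeration of all label assignments when
#' `n_x + n_y <= 12`, otherwise asymptotic via the Kolmogorov
#' distribution with effective size `n_x n_y / (n_x + n_y)`.
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with `D`, `p`, `method`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) abort_validation("x and y must be non-empty")
  nx <- length(x); ny <- length(y)
  ks_d <- function(xi, yi) {
    grid <- sort(unique(c(xi, yi)))
    Fx <- vapply(grid, function(g) mean(xi <= g), numeric(1))
    Fy <- vapply(grid, function(g) mean(yi <= g), numeric(1))
    max(abs(Fx - Fy))
  }
  D <- ks_d(x, y)
  N <- nx + ny
  if (N <= 12) {
    pooled <- c(x, y)
    combs <- utils::combn(N, nx)
    ds <- apply(combs, 2, function(idx)
      ks_d(pooled[idx], pooled[-idx]))
    return(list(D = D, p = mean(ds >= D - 1e-12), method = "exact"))
  }
  ne <- nx * ny / N
  list(D = D, p = kolmogorov_q(sqrt(ne) * D), method = "asymptotic")
}

#' Genotype comparison of diversity and specialization
#'
#' Splits per-cell diversity and specialization by genotype, compares each
#' by the two-sample KS test and reports the direction of the median
#' differences.
#'
#' @param m `cell_feature_matrix` with both genotypes present.
#' @return list with `diversity` / `specialization` sublists (per-genotype
#'   values, `ks`, `median_diff` = MT - WT) and `directions` summary.
#' @export
genotype_heterogeneity <- function(m) {
  if (!all(c("WT", "MT") %in% m$genotype))
    abort_validation("both genotypes must be present")
  ep <- entropy_profiles(m)
  split_by <- function(v) split(v, ep$genotype)
  out <- lapply(list(diversity = ep$diversity,
                     specialization = ep$specialization), function(v) {
    g <- split_by(v)
    list(WT = g$WT, MT = g$MT, ks = ks_two_sample(g$MT, g$WT),
         median_diff = stats::median(g$MT) - stats::median(g$WT))
  })
  out$directions <- c(
    diversity = ifelse(out$diversity$median_diff > 0, "MT>WT", "MT<=WT"),
    specialization = ifelse(out$specialization$median_diff < 0,
                            "MT<WT", "MT>=WT"))
  out
}

#' Rank motifs by differential accessible binding sites
#'
#' Per motif, counts peaks carrying the motif in the MT peak set minus the
#' count in the WT peak set, ranked descending.
#'
#' @param motif_hits_mt logical matrix, MT peaks x motifs.
#' @param motif_hits_wt logical matrix, WT peaks x motifs (same columns).
#' @param top_k optional head size for the `top` element.
#' @return data.frame ranked by `delta` = count_MT - count_WT, plus a
#'   `top` attribute with the first `top_k` motifs.
#' @export
motif_accessibility_ranking <- function(motif_hits_mt, motif_hits_wt,
                                        top_k = 50) {
  if (!identical(colnames(motif_hits_mt), colnames(motif_hits_wt)))
    abort_validation("motif columns must match between genotypes")
  cmt <- colSums(motif_hits_mt)
  cwt <- colSums(motif_hits_wt)
  out <- data.frame(motif = colnames(motif_hits_mt),
                    count_MT = as.integer(cmt), count_WT = as.integer(cwt),
                    delta = as.integer(cmt - cwt), stringsAsFactors = FALSE)
  out <- out[order(-out$delta, out$motif), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "top") <- utils::head(out$motif, top_k)
  out
}

#' Write / read a cell x feature matrix as MTX + metadata TSV
#'
#' @param m `cell_feature_matrix`.
#' @param dir output directory (matrix.mtx, cells.tsv, features.tsv).
#' @return `dir` (write) or a `cell_feature_matrix` (read).
#' @export
write_cell_matrix <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(m$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(cell_id = m$cell_id, genotype = m$genotype),
                     file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(colnames(m$counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @rdname write_cell_matrix
#' @export
read_cell_matrix <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  meta <- utils::read.table(file.path(dir, "cells.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  colnames(counts) <- readLines(file.path(dir, "features.tsv"))
  cell_feature_matrix(counts, meta$genotype, meta$cell_id)
}
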