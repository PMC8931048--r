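#' Mann-Whitney U test (midranks, exact for small samples)
#'
#' Rank-sum test for a location difference between two samples. U is
#' computed from midrank-corrected rank sums. For pooled sizes
#' `n_x + n_y <= 12` the exact conditional null distribution is enumerated
#' (all label assignments of the pooled values, so ties are handled
#' exactly); otherwise a normal approximation with tie-corrected variance
#' is used.
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with `U` (for `x`), `Z`, `p_two_sided`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) abort_validation("x and y must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1)
    return(list(U = nx * ny / 2, Z = 0, p_two_sided = 1,
                method = "degenerate"))
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(pooled)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  Z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  if (N <= 12) {
    combs <- utils::combn(N, nx)
    stats_null <- apply(combs, 2, function(idx)
      sum(r[idx]) - nx * (nx + 1) / 2)
    p <- mean(abs(stats_null - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, Z = Z, p_two_sided = p, method = "exact"))
  }
  list(U = U, Z = Z, p_two_sided = 2 * stats::pnorm(-abs(Z)),
       method = "normal")
}

#' Cuzick's test for trend across ordered groups
#'
#' Rank-based trend test: with group scores \eqn{z_i} (default 1..G),
#' midranks \eqn{R} over the pooled sample of size N, the statistic is
#' \eqn{T = \sum_i z_i L_i} with \eqn{L_i} the rank sum of group i. Under
#' the null \eqn{E[T] = (N+1)/2 \sum z_i n_i} and
#' \eqn{Var[T] = (N+1)/12 (N \sum z_i^2 n_i - (\sum z_i n_i)^2)} times the
#' tie correction \eqn{1 - \sum(t^3 - t)/(N^3 - N)}. Two-sided p from the
#' normal approximation; set `B > 0` for an additional seeded permutation
#' p-value.
#'
#' @param groups list of numeric vectors, in trend order.
#' @param scores optional numeric group scores (default `1:G`).
#' @param B permutation resamples for the cross-check p (0 = skip).
#' @param seed seed for the permutation p.
#' @return list of class `trend_result`: `T`, `E_T`, `Var_T`, `Z`,
#'   `p_two_sided`, `group_sizes`, `scores`, optionally `p_perm`.
#' @export
cuzick_trend <- function(groups, scores = NULL, B = 0, seed = 1) {
  if (!is.list(groups) || length(groups) < 2)
    abort_validation("need >= 2 ordered groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) {
    warning("empty group(s) dropped from trend test")
    keep <- sizes > 0
    groups <- groups[keep]
    if (!is.null(scores)) scores <- scores[keep]
    sizes <- lengths(groups)
    if (length(groups) < 2)
      abort_validation("fewer than 2 non-empty groups")
  }
  G <- length(groups)
  if (is.null(scores)) scores <- seq_len(G)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  gidx <- rep(seq_len(G), sizes)
  z <- scores[gidx]
  Tstat <- sum(z * r)
  szn <- sum(scores * sizes)
  E_T <- (N + 1) / 2 * szn
  tie_tab <- table(pooled)
  tie_corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  Var_T <- (N + 1) / 12 * (N * sum(scores^2 * sizes) - szn^2) * tie_corr
  Z <- if (Var_T > 0) (Tstat - E_T) / sqrt(Var_T) else 0
  p <- if (Var_T > 0) 2 * stats::pnorm(-abs(Z)) else 1
  out <- list(T = Tstat, E_T = E_T, Var_T = Var_T, Z = Z, p_two_sided = p,
              group_sizes = as.integer(sizes), scores = scores)
  if (B > 0) {
    set.seed(seed)
    obs_dev <- abs(Tstat - E_T)
    hits <- 0L
    for (b in seq_len(B)) {
      Tb <- sum(z * sample(r))
      if (abs(Tb - E_T) >= obs_dev - 1e-12) hits <- hits + 1L
    }
    out$p_perm <- (hits + 1) / (B + 1)
  }
  class(out) <- "trend_result"
  out
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Cuzick trend: T = %.3f, Z = %.3f, p = %.4g (groups: %s)\n",
              x$T, x$Z, x$p_two_sided,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

# Per-gene expression summary: median over the genotype's samples of
# log(count + 1).
summarize_expression <- function(expr, samples, genotype) {
  cols <- samples$sample_id[samples$genotype == genotype]
  cols <- intersect(cols, colnames(expr))
  if (!length(cols))
    abort_validation("no expression columns for genotype %s", genotype)
  apply(log(expr[, cols, drop = FALSE] + 1), 1, stats::median)
}

#' Promoter-state occupancy vs expression
#'
#' For one chromatin state (by semantic label): Mann-Whitney on expression
#' between genes with any promoter occupancy of the state and genes with
#' none (presence test), and Cuzick's trend across the five occupancy
#' buckets (dosage test). Expression is the within-genotype median of
#' log(count + 1) per gene.
#'
#' @param occ `promoter_occupancy`.
#' @param expr gene x sample count matrix (rownames = gene ids).
#' @param samples sample data.frame (`sample_id`, `genotype`).
#' @param genotype genotype whose samples summarize expression
#'   (default "MT", matching the upstream analyses).
#' @param state semantic state label (e.g. "active_promoter").
#' @return list with `presence` (Mann-Whitney), `trend` (Cuzick),
#'   `per_bucket` expression lists, `n_present`, `n_absent`.
#' @export
occupancy_expression_table <- function(occ, expr, samples, genotype = "MT",
                                       state) {
  if (!state %in% occ$labels)
    abort_validation("state label '%s' not in model (have: %s)", state,
                     paste(unique(occ$labels), collapse = ", "))
  cols <- which(occ$labels == state)
  o <- rowSums(occ[[genotype]]$occ[, cols, drop = FALSE])
  genes <- intersect(occ$gene_id, rownames(expr))
  o <- o[genes]
  e <- summarize_expression(expr[genes, , drop = FALSE], samples, genotype)
  present <- o > 0
  if (!any(present)) {
    warning(sprintf("state %s never occupies a promoter; presence test skipped",
                    state))
    return(list(presence = NULL, trend = NULL, per_bucket = NULL,
                n_present = 0L, n_absent = length(o)))
  }
  presence <- if (any(!present)) mann_whitney(e[present], e[!present])
              else NULL
  buckets <- occupancy_bucket(o)
  per_bucket <- split(e, buckets)
  nonempty <- per_bucket[lengths(per_bucket) > 0]
  trend <- if (length(nonempty) >= 2)
    cuzick_trend(nonempty, scores = which(lengths(per_bucket) > 0))
  else NULL
  list(presence = presence, trend = trend, per_bucket = per_bucket,
       n_present = sum(present), n_absent = sum(!present))
}

#' State-expression association summary across all labels
#'
#' @inheritParams occupancy_expression_table
#' @return data.frame with one row per distinct state label: state,
#'   n_present, n_absent, U, Z, p, trend_Z, trend_p.
#' @export
state_expression_report <- function(occ, expr, samples, genotype = "MT") {
  labs <- unique(occ$labels)
  rows <- lapply(labs, function(lab) {
    r <- occupancy_expression_table(occ, expr, samples, genotype, lab)
    data.frame(state = lab, n_present = r$n_present, n_absent = r$n_absent,
               U = if (is.null(r$presence)) NA else r$presence$U,
               Z = if (is.null(r$presence)) NA else r$presence$Z,
               p = if (is.null(r$presence)) NA else r$presence$p_two_sided,
               trend_Z = if (is.null(r$trend)) NA else r$trend$Z,
               trend_p = if (is.null(r$trend)) NA else r$trend$p_two_sided)
  })
  do.call(rbind, rows)
}
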