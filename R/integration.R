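ols_fit <- function(X, y) {
  # X includes the intercept column; QR-based OLS with SEs and hat values
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    cn <- colnames(X)
    abort_validation("rank-deficient design: dependent column(s) %s",
                     paste(cn[qx$pivot[(qx$rank + 1):ncol(X)]],
                           collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(diag(XtXinv) * s2, 0))
  Q <- qr.Q(qx)
  h <- rowSums(Q^2)
  list(beta = as.numeric(beta), se = se, residuals = as.numeric(res),
       s2 = s2, h = h, qr = qx,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

r2_of <- function(X, y, cols) {
  # R^2 of the model with intercept plus the covariate columns in `cols`
  if (!length(cols)) return(0)
  Xs <- cbind(1, X[, cols, drop = FALSE])
  qx <- qr(Xs)
  res <- qr.resid(qx, y)
  1 - sum(res^2) / sum((y - mean(y))^2)
}

#' LMG relative-importance decomposition of R-squared
#'
#' The LMG share of covariate j is the average over all `k!` covariate
#' orderings of the increment in R-squared when j enters after its
#' predecessors; computed exactly by subset enumeration with multiplicity
#' weights `|S|! (k - |S| - 1)! / k!`. Shares are nonnegative for OLS and
#' sum exactly to the full-model R-squared.
#'
#' @param design gene x covariate numeric matrix or data.frame (no
#'   intercept column).
#' @param y response vector.
#' @param exact_max maximum k for exact enumeration (default 10).
#' @param n_orderings when `k > exact_max`, number of sampled orderings.
#' @param seed seed for ordering sampling.
#' @return named numeric vector of shares with attribute `r2`.
#' @export
lmg_shares <- function(design, y, exact_max = 10, n_orderings = NULL,
                       seed = 1) {
  X <- as.matrix(design)
  k <- ncol(X)
  if (nrow(X) <= k + 1) abort_validation("need n > k + 1 observations")
  if (k > exact_max && is.null(n_orderings))
    abort_validation(
      "k = %d exceeds the exact enumeration bound (%d); pass n_orderings to subsample",
      k, exact_max)
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(k))
  if (k <= exact_max) {
    # R^2 for every subset, indexed by bitmask
    r2s <- numeric(2^k)
    for (mask in seq_len(2^k - 1)) {
      cols <- which(bitwAnd(mask, bitwShiftL(1, seq_len(k) - 1)) != 0)
      r2s[mask + 1] <- r2_of(X, y, cols)
    }
    shares <- numeric(k)
    lf <- lfactorial
    for (j in seq_len(k)) {
      bit_j <- bitwShiftL(1, j - 1)
      others <- setdiff(seq_len(k), j)
      for (msub in 0:(2^(k - 1) - 1)) {
        cols <- others[which(bitwAnd(msub,
                                     bitwShiftL(1, seq_len(k - 1) - 1)) != 0)]
        mask <- sum(bitwShiftL(1, cols - 1))
        s <- length(cols)
        w <- exp(lf(s) + lf(k - s - 1) - lf(k))
        shares[j] <- shares[j] +
          w * (r2s[bitwOr(mask, bit_j) + 1] - r2s[mask + 1])
      }
    }
  } else {
    set.seed(seed)
    shares <- numeric(k)
    for (b in seq_len(n_orderings)) {
      ord <- sample(k)
      prev <- 0
      cols <- integer(0)
      for (j in ord) {
        cols <- c(cols, j)
        cur <- r2_of(X, y, cols)
        shares[j] <- shares[j] + (cur - prev)
        prev <- cur
      }
    }
    shares <- shares / n_orderings
  }
  names(shares) <- cn
  attr(shares, "r2") <- r2_of(X, y, seq_len(k))
  shares
}

vif_of <- function(X) {
  k <- ncol(X)
  vapply(seq_len(k), function(j) {
    r2 <- r2_of(X[, -j, drop = FALSE], X[, j], seq_len(k - 1))
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1))
}

#' Multivariable log-linear model of expression on epigenetic covariates
#'
#' Fits `ln(count + pseudocount)` by OLS on the covariate table (typically
#' active/inactive promoter-state occupancy in percent, gene-body
#' methylation percent, hydroxymethylation presence and distal-enhancer
#' presence). Coefficients are reported both raw and as multiplicative
#' effects `e^beta - 1`. A single fit-exclude-refit pass removes
#' observations with leverage `h > 2k/n` or Cook's distance
#' `D > 4/(n - k - 1)` (k = number of covariates), then refits once.
#' LMG shares and VIFs are computed on the retained observations.
#'
#' @param design gene x covariate data.frame/matrix (no intercept).
#' @param counts expression counts (or any nonnegative response), one per
#'   design row; a vector, typically per-gene median counts or one
#'   sample's counts.
#' @param pseudocount added before the natural log (default 1).
#' @return object of class `integration_fit`.
#' @export
fit_integration <- function(design, counts, pseudocount = 1) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  k <- ncol(X)
  n <- nrow(X)
  if (n <= k + 1) abort_validation("need n > k + 1")
  if (any(!is.finite(X))) abort_validation("non-finite covariates")
  y <- log(counts + pseudocount)
  Xd <- cbind(`(Intercept)` = 1, X)
  fit0 <- ols_fit(Xd, y)
  # diagnostics on the initial fit; Cook's D with k = covariate count
  h <- fit0$h
  D <- fit0$residuals^2 * h / (k * fit0$s2 * (1 - h)^2)
  lev_cut <- 2 * k / n
  inf_cut <- 4 / (n - k - 1)
  excl_lev <- h > lev_cut
  excl_inf <- D > inf_cut
  excluded <- which(excl_lev | excl_inf)
  reason <- ifelse(excl_lev[excluded] & excl_inf[excluded],
                   "leverage+influence",
                   ifelse(excl_lev[excluded], "leverage", "influence"))
  keep <- setdiff(seq_len(n), excluded)
  if (length(keep) <= k + 1)
    abort_validation("n <= k + 1 after diagnostic exclusion")
  fit <- ols_fit(Xd[keep, , drop = FALSE], y[keep])
  z <- fit$beta / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  shares <- lmg_shares(X[keep, , drop = FALSE], y[keep])
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(
    terms = c("(Intercept)", colnames(X)),
    betas = fit$beta, se = fit$se, wald_z = z, p = p,
    effects = expm1(fit$beta),
    r2 = fit$r2,
    lmg_shares = shares,
    excluded = data.frame(id = ids[excluded],
                          h = h[excluded], cook_d = D[excluded],
                          reason = reason, stringsAsFactors = FALSE),
    leverage_cutoff = lev_cut, influence_cutoff = inf_cut,
    vif = stats::setNames(vif_of(X[keep, , drop = FALSE]), colnames(X)),
    n = n, n_used = length(keep), k = k, pseudocount = pseudocount,
    diagnostics = data.frame(id = ids, h = h, cook_d = D,
                             excluded = seq_len(n) %in% excluded)
  ), class = "integration_fit")
}

#' @export
print.integration_fit <- function(x, ...) {
  cat(sprintf("integration_fit: n = %d (%d used), R2 = %.4f\n",
              x$n, x$n_used, x$r2))
  print(data.frame(term = x$terms, beta = round(x$betas, 4),
                   effect = round(x$effects, 4), se = round(x$se, 4),
                   z = round(x$wald_z, 2), p = signif(x$p, 3)))
  invisible(x)
}

#' Relative-importance ranking from an integration fit
#'
#' @param fit `integration_fit`.
#' @return data.frame ranked by LMG share: covariate, lmg_share,
#'   share_pct (percent of R-squared), effect, p.
#' @export
relative_importance_report <- function(fit) {
  sh <- fit$lmg_shares
  ord <- order(-sh)
  idx <- match(names(sh), fit$terms)
  out <- data.frame(covariate = names(sh)[ord],
                    lmg_share = as.numeric(sh[ord]),
                    share_pct = 100 * as.numeric(sh[ord]) / attr(sh, "r2"),
                    effect = fit$effects[idx][ord],
                    p = fit$p[idx][ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the standard integration design from pipeline outputs
#'
#' Covariates: active-state promoter occupancy (percent; states labelled
#' active promoter or active enhancer), inactive occupancy (poised +
#' repressed, percent), gene-body methylation percent,
#' hydroxymethylation presence, distal-enhancer presence.
#'
#' @param occ `promoter_occupancy`.
#' @param meth `methylation_summary`.
#' @param interactions `cis_interactions`.
#' @param genotype occupancy genotype (default "MT").
#' @return data.frame with rownames = gene ids, one column per covariate.
#' @export
integration_design <- function(occ, meth, interactions, genotype = "MT") {
  genes <- intersect(occ$gene_id, meth$gene_id)
  o <- occ[[genotype]]$occ[genes, , drop = FALSE]
  act_cols <- which(occ$labels %in% c("active_promoter", "active_enhancer"))
  inact_cols <- which(occ$labels %in% c("poised_promoter", "repressed"))
  m <- meth[match(genes, meth$gene_id), ]
  enh <- as.numeric(genes %in% interactions$gene_id)
  X <- data.frame(
    active_occ = 100 * rowSums(o[, act_cols, drop = FALSE]),
    inactive_occ = 100 * rowSums(o[, inact_cols, drop = FALSE]),
    mc_pct = 100 * m$mc_fraction,
    hmc_present = as.numeric(m$hmc_present),
    enh_present = enh)
  rownames(X) <- genes
  X
}
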