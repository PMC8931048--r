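# Independent brute-force oracles. These deliberately share no code with
# the implementation: nested loops, exhaustive enumeration, direct formulas.

brute_overlap_pairs <- function(a, b, min_bp = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_bp) out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(query = integer(0),
                                      subject = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2])
}

pairs_key <- function(p) sort(paste(p$query, p$subject))

# bp covered in [lo, hi) by a set of intervals, counted base by base
brute_coverage_bp <- function(lo, hi, chrom, peaks) {
  covered <- logical(hi - lo)
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != chrom) next
    s <- max(peaks$start[i], lo); e <- min(peaks$end[i], hi)
    if (s < e) covered[(s - lo + 1):(e - lo)] <- TRUE
  }
  sum(covered)
}

# Viterbi by exhaustive path enumeration (<= K^T paths)
brute_viterbi <- function(obs, phi, A, pi) {
  Tn <- nrow(obs); K <- nrow(phi)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  best <- NULL; best_lp <- -Inf
  for (r in seq_len(nrow(grid))) {
    path <- grid[r, ]
    lp <- log(pi[path[1]])
    for (t in seq_len(Tn)) {
      lp <- lp + sum(obs[t, ] * log(phi[path[t], ]) +
                       (1 - obs[t, ]) * log(1 - phi[path[t], ]))
      if (t > 1) lp <- lp + log(A[path[t - 1], path[t]])
    }
    if (lp > best_lp) { best_lp <- lp; best <- path }
  }
  list(path = as.integer(best), logp = best_lp)
}

# all permutations of a small vector
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# exact Cuzick permutation p over all distinct group assignments
cuzick_exact_perm <- function(groups, scores = seq_along(groups)) {
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  N <- length(pooled)
  r <- rank(pooled)
  z_for <- function(assign) {
    # assign: group index per pooled position
    sum(scores[assign] * r)
  }
  obs_assign <- rep(seq_along(groups), sizes)
  Tobs <- z_for(obs_assign)
  ET <- (N + 1) / 2 * sum(scores * sizes)
  perms <- all_perms(seq_len(N))
  Ts <- vapply(perms, function(p) z_for(obs_assign[p]), numeric(1))
  mean(abs(Ts - ET) >= abs(Tobs - ET) - 1e-9)
}

# Fisher combination p by direct formula
fisher_direct <- function(pvals) {
  stats::pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals),
                lower.tail = FALSE)
}

# exact two-sided Fisher test p via hypergeometric enumeration
fisher_exact_brute <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; m <- a + c; N <- n1 + n2
  dens <- vapply(max(0, m - n2):min(m, n1), function(x)
    stats::dhyper(x, n1, n2, m), numeric(1))
  obs <- stats::dhyper(a, n1, n2, m)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# LMG by direct enumeration of all k! orderings using lm()
lmg_brute <- function(X, y) {
  k <- ncol(X)
  X <- as.matrix(X)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    summary(stats::lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  shares <- numeric(k)
  ords <- all_perms(seq_len(k))
  for (ord in ords) {
    prev <- 0; cols <- integer(0)
    for (j in ord) {
      cols <- c(cols, j)
      cur <- r2(cols)
      shares[j] <- shares[j] + cur - prev
      prev <- cur
    }
  }
  shares / length(ords)
}

# naive PWM scan: every offset, both strands, explicit loops
brute_pwm_hit <- function(seq, pwm, score_frac = 0.8) {
  lo <- log2(pwm$matrix) - rep(log2(pwm$background),
                               each = nrow(pwm$matrix))
  maxs <- sum(apply(lo, 1, max))
  sc <- function(s) {
    ch <- strsplit(s, "")[[1]]
    w <- nrow(lo); L <- length(ch); best <- -Inf
    if (L < w) return(best)
    for (off in 0:(L - w)) {
      tot <- 0
      for (p in 1:w) {
        base <- ch[off + p]
        if (base != "N")
          tot <- tot + lo[p, match(base, c("A", "C", "G", "T"))]
      }
      best <- max(best, tot)
    }
    best
  }
  rc <- paste(rev(chartr("ACGTN", "TGCAN",
                         strsplit(seq, "")[[1]])), collapse = "")
  max(sc(seq), sc(rc)) >= score_frac * maxs
}
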