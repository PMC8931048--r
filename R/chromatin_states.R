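#' Marks used for chromatin-state segmentation
#'
#' The five tracks entering the hidden Markov model, in canonical order:
#' H3K4me1, H3K4me3, H3K27ac, H3K27me3, ATAC. H2AK119ub is analysed
#' separately and is not an HMM track.
#' @export
hmm_marks <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3", "ATAC")

#' Assemble binarized tracks
#'
#' @param obs list of sample matrices (bins x marks, 0/1), or a single
#'   stacked matrix of `n_samples * total_bins` rows.
#' @param samples data.frame with columns `sample_id` and `genotype`
#'   ("WT"/"MT").
#' @param marks mark names, one per observation column.
#' @param layout `genome_layout`.
#' @return object of class `binarized_tracks` holding the stacked
#'   observation matrix (samples concatenated in order).
#' @export
binarized_tracks <- function(obs, samples, marks, layout) {
  if (is.list(obs)) obs <- do.call(rbind, obs)
  obs <- as.matrix(obs)
  B <- total_bins(layout)
  S <- nrow(samples)
  if (nrow(obs) != S * B || ncol(obs) != length(marks))
    abort_validation("observation matrix is %d x %d, expected %d x %d",
                     nrow(obs), ncol(obs), S * B, length(marks))
  if (!all(obs %in% c(0, 1)))
    abort_validation("binarized observations must be 0/1")
  if (!all(samples$genotype %in% c("WT", "MT")))
    abort_validation("genotype must be 'WT' or 'MT'")
  storage.mode(obs) <- "integer"
  colnames(obs) <- marks
  structure(list(obs = obs, samples = samples, marks = marks,
                 layout = layout),
            class = "binarized_tracks")
}

#' @export
print.binarized_tracks <- function(x, ...) {
  cat("binarized_tracks:", nrow(x$samples), "samples x",
      total_bins(x$layout), "bins x", length(x$marks), "marks\n")
  invisible(x)
}

sample_rows <- function(tracks, s) {
  B <- total_bins(tracks$layout)
  ((s - 1) * B + 1):(s * B)
}

# Sequence boundaries (chromosomes within samples) over the stacked matrix,
# 0-based [start, end) as required by the C++ kernels.
seq_bounds <- function(layout, n_samples) {
  B <- total_bins(layout)
  starts <- integer(0); ends <- integer(0)
  for (s in seq_len(n_samples)) {
    off <- (s - 1) * B
    starts <- c(starts, off + layout$bin_offsets)
    ends <- c(ends, off + layout$bin_offsets + layout$n_bins)
  }
  list(starts = as.integer(starts), ends = as.integer(ends))
}

#' Binarize per-bin count tracks
#'
#' A bin is flagged present (1) for a mark when its count is improbably
#' large under a Poisson background whose rate is that sample's genome-wide
#' mean count per bin for the mark: flag iff `P(X >= x) < p_threshold`.
#'
#' @param counts list of per-sample count matrices (bins x marks), or one
#'   stacked matrix.
#' @param samples sample data.frame (`sample_id`, `genotype`).
#' @param marks mark names.
#' @param layout `genome_layout`.
#' @param p_threshold Poisson upper-tail threshold (default 1e-4).
#' @return `binarized_tracks`.
#' @export
binarize <- function(counts, samples, marks, layout, p_threshold = 1e-4) {
  if (is.list(counts)) counts <- do.call(rbind, counts)
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort_validation("counts must be non-negative")
  B <- total_bins(layout)
  S <- nrow(samples)
  out <- matrix(0L, nrow(counts), ncol(counts))
  for (s in seq_len(S)) {
    rows <- ((s - 1) * B + 1):(s * B)
    for (m in seq_along(marks)) {
      x <- counts[rows, m]
      lambda <- mean(x)
      if (lambda == 0) {
        warning(sprintf("all-zero track: sample %s mark %s",
                        samples$sample_id[s], marks[m]))
        next
      }
      # P(X >= x) = ppois(x - 1, lambda, lower.tail = FALSE)
      tail <- stats::ppois(x - 1, lambda, lower.tail = FALSE)
      out[rows, m] <- as.integer(tail < p_threshold)
    }
  }
  binarized_tracks(out, samples, marks, layout)
}

clamp_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

log_emissions <- function(obs, phi) {
  # obs: T x M in {0,1}; phi: K x M -> T x K log product-Bernoulli
  obs %*% t(log(phi)) + (1 - obs) %*% t(log(1 - phi))
}

#' Semantic labels from emission probabilities
#'
#' Pure function of the emission matrix (threshold 0.5 = "high"), stable
#' under state permutation. Requires the five canonical marks.
#'
#' @param phi K x M emission matrix with columns named by mark.
#' @return character vector of K labels.
#' @export
label_states <- function(phi) {
  need <- hmm_marks
  if (!all(need %in% colnames(phi)))
    abort_validation("emission matrix must have columns %s",
                     paste(need, collapse = ", "))
  hi <- phi >= 0.5
  k4me1 <- hi[, "H3K4me1"]; k4me3 <- hi[, "H3K4me3"]
  k27ac <- hi[, "H3K27ac"]; k27me3 <- hi[, "H3K27me3"]
  atac <- hi[, "ATAC"]
  lab <- rep("other", nrow(phi))
  lab[atac & !k4me1 & !k4me3 & !k27ac & !k27me3] <- "accessible"
  lab[k27me3 & !k4me3 & !k27ac] <- "repressed"
  lab[k4me1 & !k27ac & !k4me3] <- "inactive_enhancer"
  lab[k4me1 & k27ac & !k4me3] <- "active_enhancer"
  lab[k4me3 & k27me3] <- "poised_promoter"
  lab[k4me3 & k27ac] <- "active_promoter"
  lab[!k4me1 & !k4me3 & !k27ac & !k27me3 & !atac] <- "quiescent"
  lab
}

new_state_model <- function(phi, A, pi, loglik, marks, converged = TRUE) {
  K <- nrow(phi)
  dimnames(phi) <- list(paste0("S", seq_len(K)), marks)
  labels <- if (all(hmm_marks %in% marks)) label_states(phi)
            else rep("unlabelled", K)
  structure(list(K = K, phi = phi, A = A, pi = pi, labels = labels,
                 loglik = loglik, marks = marks, converged = converged),
            class = "chrom_state_model")
}

#' @export
print.chrom_state_model <- function(x, ...) {
  cat("chrom_state_model: K =", x$K, " loglik =", format(x$loglik), "\n")
  print(cbind(round(x$phi, 3), label = x$labels), quote = FALSE)
  invisible(x)
}

#' Fit a product-Bernoulli hidden Markov model
#'
#' Baum-Welch EM over the concatenation of all samples' bin sequences
#' (chromosome boundaries break transitions). Emission of observation
#' vector o in state k is the product of independent Bernoullis,
#' \eqn{\prod_m \phi_{km}^{o_m} (1-\phi_{km})^{1-o_m}}. The best of
#' `n_restarts` random restarts (by log-likelihood) is returned.
#'
#' @param tracks `binarized_tracks`.
#' @param K number of states (5-15 is the usual range; K = 7 is the
#'   default model used downstream).
#' @param n_restarts random restarts (default 5).
#' @param seed integer seed; restarts are seeded deterministically from it.
#' @param tol relative log-likelihood change declaring convergence
#'   (default 1e-4).
#' @param max_iter EM iteration cap (default 200).
#' @return `chrom_state_model`; attribute `loglik_trace` carries the EM
#'   log-likelihood sequence of the winning restart.
#' @export
fit_hmm <- function(tracks, K = 7, n_restarts = 5, seed = 1, tol = 1e-4,
                    max_iter = 200) {
  if (K < 1) abort_validation("K must be >= 1")
  obs <- tracks$obs
  M <- ncol(obs)
  bounds <- seq_bounds(tracks$layout, nrow(tracks$samples))
  if (K == 1) {
    phi <- matrix(clamp_prob(colMeans(obs)), 1, M)
    logB <- log_emissions(obs, phi)
    ll <- sum(logB)
    return(new_state_model(phi, matrix(1, 1, 1), 1, ll, tracks$marks))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed * 1000L + r)
    phi <- matrix(stats::runif(K * M, 0.1, 0.9), K, M)
    A <- matrix(stats::runif(K * K, 0.5, 1), K, K) + diag(K) * K
    A <- A / rowSums(A)
    pi <- rep(1 / K, K)
    ll_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      logB <- log_emissions(obs, phi)
      e <- hmm_estep_cpp(logB, A, pi, bounds$starts, bounds$ends)
      ll <- e$loglik
      trace <- c(trace, ll)
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol * abs(ll_prev)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
      g <- e$gamma
      A <- e$xi / rowSums(e$xi)
      pi <- e$gamma1 / sum(e$gamma1)
      phi <- clamp_prob(crossprod(g, obs) / colSums(g))
    }
    cand <- new_state_model(phi, A, pi, trace[length(trace)],
                            tracks$marks, converged)
    attr(cand, "loglik_trace") <- trace
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best restart")
  best
}

#' Decode chromatin states
#'
#' @param model `chrom_state_model`.
#' @param tracks `binarized_tracks` with the model's mark order.
#' @param method "viterbi" (jointly most probable path) or "posterior"
#'   (per-bin argmax of the forward-backward posterior).
#' @return `state_map`: per-sample per-bin states plus per-genotype per-bin
#'   state frequency matrices.
#' @export
decode <- function(model, tracks, method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  if (!identical(model$marks, tracks$marks))
    abort_validation("model and tracks disagree on mark order")
  obs <- tracks$obs
  bounds <- seq_bounds(tracks$layout, nrow(tracks$samples))
  logB <- log_emissions(obs, model$phi)
  posterior <- NULL
  if (method == "viterbi") {
    path <- hmm_viterbi_cpp(logB, log(model$A), log(model$pi),
                            bounds$starts, bounds$ends)
  } else {
    p <- hmm_posterior_cpp(logB, model$A, model$pi,
                           bounds$starts, bounds$ends)
    path <- max.col(p$gamma, ties.method = "first")
    posterior <- p$gamma[cbind(seq_along(path), path)]
  }
  B <- total_bins(tracks$layout)
  S <- nrow(tracks$samples)
  states <- matrix(as.integer(path), nrow = S, ncol = B, byrow = TRUE)
  rownames(states) <- tracks$samples$sample_id
  freq <- lapply(c(WT = "WT", MT = "MT"), function(g) {
    rows <- which(tracks$samples$genotype == g)
    if (!length(rows)) return(NULL)
    f <- vapply(seq_len(model$K), function(k)
      colMeans(states[rows, , drop = FALSE] == k), numeric(B))
    t(f)  # K x B
  })
  structure(list(states = states, posterior = posterior, freq = freq,
                 samples = tracks$samples, layout = tracks$layout,
                 K = model$K, labels = model$labels),
            class = "state_map")
}

#' @export
print.state_map <- function(x, ...) {
  cat("state_map:", nrow(x$states), "samples x", ncol(x$states),
      "bins, K =", x$K, "\n")
  invisible(x)
}

# Global bin index for each of the 2*flank/bin_width promoter positions of a
# gene, strand-oriented (position 1 = most upstream). NA rows mark genes
# whose window leaves the decoded region.
promoter_bin_matrix <- function(genes, layout, flank) {
  bw <- layout$bin_width
  n_pos <- as.integer(round(2 * flank / bw))
  if (n_pos < 1) abort_validation("flank smaller than one bin")
  res <- matrix(NA_integer_, nrow(genes), n_pos)
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    if (!chrom %in% layout$chrom_names) next
    mid <- genes$tss[i] - flank + (seq_len(n_pos) - 0.5) * bw
    bins <- floor(mid / bw)
    if (any(bins < 0) || any(bins >= layout$n_bins[chrom])) next
    bins <- layout$bin_offsets[chrom] + bins + 1
    if (genes$strand[i] == "-") bins <- rev(bins)
    res[i, ] <- as.integer(bins)
  }
  res
}

#' Genotype chromatin-state contrast over promoter windows
#'
#' Subtracts WT from MT consensus-state frequencies position-by-position
#' across strand-oriented promoter windows, and tabulates the K x K
#' consensus-state transitions (WT state -> MT state) over promoter bins.
#'
#' @param map `state_map`.
#' @param genes gene-model table.
#' @param flank promoter half-width (default 2000).
#' @return list with `delta` (positions x states, f_MT - f_WT), and
#'   `transition_matrix` (K x K counts), `n_genes_used`, `n_genes_skipped`.
#' @export
genotype_contrast <- function(map, genes, flank = 2000) {
  pb <- promoter_bin_matrix(genes, map$layout, flank)
  ok <- stats::complete.cases(pb)
  if (any(!ok))
    warning(sprintf("%d gene(s) with promoter outside decoded region skipped",
                    sum(!ok)))
  pb <- pb[ok, , drop = FALSE]
  if (!nrow(pb)) abort_validation("no gene promoter lies in decoded region")
  rows_wt <- which(map$samples$genotype == "WT")
  rows_mt <- which(map$samples$genotype == "MT")
  K <- map$K
  n_pos <- ncol(pb)
  cs <- function(rows) {
    # genes x positions consensus states for one genotype
    t(vapply(seq_len(nrow(pb)), function(i) {
      sub <- map$states[rows, pb[i, ], drop = FALSE]
      vapply(seq_len(n_pos), function(p) {
        tb <- tabulate(sub[, p], K)
        which.max(tb)
      }, integer(1))
    }, integer(n_pos)))
  }
  wt <- cs(rows_wt)
  mt <- cs(rows_mt)
  f <- function(m) {
    # positions x K frequency of consensus states across genes
    vapply(seq_len(K), function(k) colMeans(m == k), numeric(n_pos))
  }
  delta <- f(mt) - f(wt)
  rownames(delta) <- sprintf("pos%+d", seq_len(n_pos) - n_pos / 2 - 1)
  colnames(delta) <- paste0("S", seq_len(K))
  tm <- matrix(0L, K, K,
               dimnames = list(paste0("WT_S", seq_len(K)),
                               paste0("MT_S", seq_len(K))))
  for (k in seq_len(K)) for (j in seq_len(K))
    tm[k, j] <- sum(wt == k & mt == j)
  list(delta = delta, transition_matrix = tm,
       n_genes_used = nrow(pb), n_genes_skipped = sum(!ok))
}

occupancy_bucket <- function(frac) {
  cut(frac, breaks = c(-Inf, 0, 0.25, 0.5, 0.75, 1),
      labels = c("0", "(0-25]", "(25-50]", "(50-75]", "(75-100]"))
}

#' Promoter state occupancy per gene and genotype
#'
#' Fraction of promoter bins decoded in each state, averaged over the
#' genotype's samples, plus the bucketed occupancy extent
#' (0, (0-25], (25-50], (50-75], (75-100] percent).
#'
#' @param map `state_map`.
#' @param genes gene-model table.
#' @param flank promoter half-width (default 2000).
#' @return list of class `promoter_occupancy`: per-genotype gene x state
#'   occupancy matrices (`occ`), bucket matrices (`bucket`), gene ids.
#' @export
promoter_occupancy <- function(map, genes, flank = 2000) {
  pb <- promoter_bin_matrix(genes, map$layout, flank)
  ok <- stats::complete.cases(pb)
  if (any(!ok))
    warning(sprintf("%d gene(s) with promoter outside decoded region skipped",
                    sum(!ok)))
  genes <- genes[ok, , drop = FALSE]
  pb <- pb[ok, , drop = FALSE]
  K <- map$K
  out <- list()
  for (g in c("WT", "MT")) {
    rows <- which(map$samples$genotype == g)
    occ <- matrix(0, nrow(pb), K,
                  dimnames = list(genes$gene_id, paste0("S", seq_len(K))))
    for (i in seq_len(nrow(pb))) {
      sub <- map$states[rows, pb[i, ], drop = FALSE]
      occ[i, ] <- tabulate(as.integer(sub), K) / length(sub)
    }
    bucket <- matrix(as.character(occupancy_bucket(as.numeric(occ))),
                     nrow = nrow(occ), dimnames = dimnames(occ))
    out[[g]] <- list(occ = occ, bucket = bucket)
  }
  structure(list(WT = out$WT, MT = out$MT, gene_id = genes$gene_id,
                 labels = map$labels),
            class = "promoter_occupancy")
}

#' Model selection across state counts
#'
#' Fits K in `k_range`, reporting BIC and whether each model discriminates
#' all six canonical chromatin-state labels (active promoter, poised
#' promoter, active enhancer, inactive enhancer, repressed, quiescent).
#' Preference order: label-covering models first, then smaller BIC; ties
#' toward smaller K (parsimony).
#'
#' @param tracks `binarized_tracks`.
#' @param k_range candidate state counts (default 5:15).
#' @param ... passed to [fit_hmm()].
#' @return data.frame with K, loglik, n_par, bic, covers_labels, selected.
#' @export
select_states <- function(tracks, k_range = 5:15, ...) {
  need <- c("active_promoter", "poised_promoter", "active_enhancer",
            "inactive_enhancer", "repressed", "quiescent")
  Tn <- nrow(tracks$obs)
  rows <- lapply(k_range, function(K) {
    m <- fit_hmm(tracks, K = K, ...)
    n_par <- K * length(tracks$marks) + K * (K - 1) + (K - 1)
    data.frame(K = K, loglik = m$loglik, n_par = n_par,
               bic = -2 * m$loglik + n_par * log(Tn),
               covers_labels = all(need %in% m$labels))
  })
  res <- do.call(rbind, rows)
  ord <- order(!res$covers_labels, res$bic, res$K)
  res$selected <- seq_len(nrow(res)) == ord[1]
  res
}

#' Write / read a chromatin-state model as JSON
#' @param model `chrom_state_model`.
#' @param path file path.
#' @return `path` (write) or the model (read).
#' @export
write_state_model <- function(model, path) {
  jsonlite::write_json(list(K = model$K, phi = model$phi, A = model$A,
                            pi = model$pi, labels = model$labels,
                            loglik = model$loglik, marks = model$marks),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_state_model
#' @export
read_state_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  phi <- unname(as.matrix(j$phi))
  new_state_model(phi, unname(as.matrix(j$A)), j$pi, j$loglik, j$marks)
}

#' Write a per-sample segmentation as BED9-like records
#'
#' Runs of equal state are merged; score is posterior x 1000 when the map
#' was posterior-decoded, else 1000.
#'
#' @param map `state_map`.
#' @param sample sample id.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(map, sample, path) {
  s <- match(sample, map$samples$sample_id)
  if (is.na(s)) abort_validation("unknown sample '%s'", sample)
  lay <- map$layout
  lines <- character(0)
  for (chrom in lay$chrom_names) {
    idx <- lay$bin_offsets[chrom] + seq_len(lay$n_bins[chrom])
    st <- map$states[s, idx]
    r <- rle(st)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    start <- starts_bin * lay$bin_width
    end <- pmin(ends_bin * lay$bin_width, lay$chrom_lengths[chrom])
    sc <- if (is.null(map$posterior)) 1000 else 1000
    lines <- c(lines, sprintf("%s\t%.0f\t%.0f\t%s\t%d\t.",
                              chrom, start, end, map$labels[r$values], sc))
  }
  writeLines(lines, path)
  invisible(path)
}
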