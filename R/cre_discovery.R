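#' Genotype-specific candidate cis-regulatory elements
#'
#' MT co-marked regions are ATAC consensus peaks overlapping (>= 1 bp) an
#' H3K27ac consensus peak; the element geometry is the ATAC peak
#' (accessibility defines the element, acetylation marks its activity). A
#' region is MT-specific when it overlaps no WT co-marked region at all,
#' and distal when it overlaps no promoter window (TSS +/- `flank`). The
#' distal MT-specific set is the default downstream set.
#'
#' @param atac_mt,k27ac_mt,atac_wt,k27ac_wt consensus interval tables.
#' @param genes gene-model table (for promoter windows).
#' @param flank promoter half-width (default 2000).
#' @param max_wt_overlap maximum tolerated bp overlap with a WT co-marked
#'   region before a candidate loses specificity (default 0 = strictest).
#' @param chrom_lengths optional lengths for promoter clipping.
#' @return data.frame of class `candidate_cres`: chrom, start, end,
#'   specific, distal. Rows are MT co-marked regions; the working set is
#'   `specific & distal`.
#' @export
genotype_specific_cres <- function(atac_mt, k27ac_mt, atac_wt, k27ac_wt,
                                   genes, flank = 2000, max_wt_overlap = 0,
                                   chrom_lengths = NULL) {
  empty <- {
    z <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), specific = logical(0),
                    distal = logical(0))
    class(z) <- c("candidate_cres", "data.frame"); z
  }
  if (nrow(atac_mt) == 0 || nrow(k27ac_mt) == 0) {
    warning("empty MT peak set(s): no candidate regions")
    return(empty)
  }
  co_mt_idx <- unique(overlap_query(atac_mt, k27ac_mt)$query)
  if (!length(co_mt_idx)) {
    warning("no MT ATAC peak co-marked by H3K27ac")
    return(empty)
  }
  cand <- atac_mt[sort(co_mt_idx), c("chrom", "start", "end"), drop = FALSE]
  rownames(cand) <- NULL
  # WT co-marked regions, same construction
  co_wt <- if (nrow(atac_wt) && nrow(k27ac_wt)) {
    idx <- unique(overlap_query(atac_wt, k27ac_wt)$query)
    atac_wt[sort(idx), , drop = FALSE]
  } else atac_wt[0, , drop = FALSE]
  specific <- rep(TRUE, nrow(cand))
  if (nrow(co_wt)) {
    hits <- overlap_query(cand, co_wt)
    if (nrow(hits)) {
      w <- overlap_widths(cand, co_wt, hits)
      bad <- unique(hits$query[w > max_wt_overlap])
      specific[bad] <- FALSE
    }
  }
  prom <- promoter_window(genes, flank, chrom_lengths)
  distal <- rep(TRUE, nrow(cand))
  distal[unique(overlap_query(cand, prom)$query)] <- FALSE
  cand$specific <- specific
  cand$distal <- distal
  class(cand) <- c("candidate_cres", "data.frame")
  cand
}

#' The default downstream CRE set: MT-specific and distal
#' @param cres `candidate_cres`.
#' @return subset interval table.
#' @export
distal_specific <- function(cres) {
  out <- cres[cres$specific & cres$distal, c("chrom", "start", "end"),
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate CREs against interval catalogs
#'
#' Flags each CRE that overlaps (>= 1 bp) a catalog region and, separately,
#' a super-enhancer catalog region; reports summary fractions.
#'
#' @param cres interval table of CREs.
#' @param catalog annotation catalog (e.g. ENCODE cCREs); may be NULL.
#' @param se_catalog super-enhancer catalog; may be NULL.
#' @return list with `flags` (data.frame annotated/super_enhancer),
#'   `frac_annotated`, `frac_super_enhancer`.
#' @export
annotate_catalog <- function(cres, catalog = NULL, se_catalog = NULL) {
  n <- nrow(cres)
  annotated <- rep(FALSE, n)
  se <- rep(FALSE, n)
  if (!is.null(catalog) && nrow(catalog))
    annotated[unique(overlap_query(cres, catalog)$query)] <- TRUE
  if (!is.null(se_catalog) && nrow(se_catalog))
    se[unique(overlap_query(cres, se_catalog)$query)] <- TRUE
  list(flags = data.frame(annotated = annotated, super_enhancer = se),
       frac_annotated = if (n) mean(annotated) else NA_real_,
       frac_super_enhancer = if (n) mean(se) else NA_real_)
}

#' Read position weight matrices in JASPAR text format
#'
#' Parses `>id name` headers followed by four `A/C/G/T [ counts... ]`
#' rows; counts are converted to column probabilities.
#'
#' @param path JASPAR-format file.
#' @return named list of `pwm` objects (matrix positions x ACGT,
#'   `background` attribute uniform).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  heads <- grep("^>", lines)
  if (!length(heads)) abort_parse("%s: no JASPAR records found", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    name <- sub("^>\\s*", "", lines[i])
    name <- strsplit(name, "\\s+")[[1]][1]
    block <- lines[(i + 1):(i + 4)]
    rows <- lapply(block, function(ln) {
      nums <- regmatches(ln, gregexpr("[0-9.]+", ln))[[1]]
      as.numeric(nums)
    })
    bases <- toupper(substr(block, 1, 1))
    if (!setequal(bases, c("A", "C", "G", "T")))
      abort_parse("%s: malformed JASPAR record '%s'", path, name)
    counts <- do.call(rbind, rows)[match(c("A", "C", "G", "T"), bases), ,
                                   drop = FALSE]
    out[[name]] <- pwm_from_counts(t(counts), name)
  }
  out
}

#' Build a PWM from a count or probability matrix
#' @param m positions x 4 matrix (columns A, C, G, T).
#' @param name motif name.
#' @param background base composition (4-simplex, default uniform).
#' @param pseudo pseudocount added to counts before normalization.
#' @return object of class `pwm`.
#' @export
pwm_from_counts <- function(m, name = "motif",
                            background = rep(0.25, 4), pseudo = 0.5) {
  m <- as.matrix(m)
  if (ncol(m) != 4) abort_validation("PWM needs 4 base columns")
  if (abs(sum(background) - 1) > 1e-6)
    abort_validation("background must sum to 1")
  probs <- (m + pseudo) / rowSums(m + pseudo)
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = probs, background = background),
            class = "pwm")
}

BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)

pwm_logodds <- function(pwm) {
  # positions x 4 log-odds; an N contributes 0 by construction downstream
  log2(pwm$matrix) - rep(log2(pwm$background), each = nrow(pwm$matrix))
}

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), ""))
}

scan_one <- function(seq, lo) {
  w <- nrow(lo)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < w) return(-Inf)
  idx <- BASE_IDX[chars]           # NA for N
  best <- -Inf
  for (off in 0:(L - w)) {
    s <- 0
    for (p in seq_len(w)) {
      b <- idx[off + p]
      if (!is.na(b)) s <- s + lo[p, b]   # N contributes 0
    }
    if (s > best) best <- s
  }
  best
}

#' Scan sequences with a PWM
#'
#' Log-odds scanning against the background at every offset on both
#' strands; a sequence is a hit when its best score reaches
#' `score_frac` times the maximum attainable score. `N` bases contribute a
#' log-odds of 0.
#'
#' @param sequences character vector over A/C/G/T/N (e.g. CRE sequences).
#' @param pwm `pwm` object.
#' @param score_frac fraction of the maximal score required (default 0.8).
#' @return logical hit vector with attribute `scores`.
#' @export
pwm_scan <- function(sequences, pwm, score_frac = 0.8) {
  lo <- pwm_logodds(pwm)
  max_score <- sum(apply(lo, 1, max))
  seqs <- toupper(sequences)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) abort_validation("sequence %d has non-ACGTN characters",
                                 which(bad)[1])
  fwd <- vapply(seqs, scan_one, numeric(1), lo = lo, USE.NAMES = FALSE)
  rev <- vapply(revcomp_chr(seqs), scan_one, numeric(1), lo = lo,
                USE.NAMES = FALSE)
  scores <- pmax(fwd, rev)
  # tolerance absorbs summation-order rounding at score_frac = 1
  hits <- is.finite(scores) & scores >= score_frac * max_score - 1e-9
  attr(hits, "scores") <- scores
  hits
}

#' Catalog enrichment of CREs against a matched background
#'
#' For each catalog entry (e.g. a transcription factor's binding regions):
#' a = foreground regions overlapping the set, b = foreground
#' non-overlapping, c/d likewise for the background; Fisher's exact test
#' (two-sided) on `[[a,b],[c,d]]` and fold enrichment
#' `(a/(a+b)) / (c/(c+d))`.
#'
#' @param foreground CRE interval table.
#' @param background matched background interval table (non-empty,
#'   disjoint from the foreground).
#' @param catalog named list of per-TF interval tables.
#' @return data.frame of class `enrichment_result`, ranked by p: label, a,
#'   b, c, d, effect_size, p.
#' @export
interval_enrichment <- function(foreground, background, catalog) {
  if (nrow(background) == 0) abort_validation("background must be non-empty")
  if (nrow(overlap_query(foreground, background)))
    abort_validation("background overlaps the foreground")
  rows <- lapply(names(catalog), function(lab) {
    tf <- catalog[[lab]]
    a <- length(unique(overlap_query(foreground, tf)$query))
    b <- nrow(foreground) - a
    cc <- length(unique(overlap_query(background, tf)$query))
    d <- nrow(background) - cc
    es <- if (cc == 0) Inf else (a / (a + b)) / (cc / (cc + d))
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    data.frame(label = lab, a = a, b = b, c = cc, d = d,
               effect_size = es, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, -out$effect_size), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Length- and chromosome-matched random background regions
#'
#' Draws `n_per` background intervals per foreground region on the same
#' chromosome with the same width, rejecting overlaps with the foreground.
#'
#' @param foreground interval table.
#' @param chrom_lengths named chromosome lengths.
#' @param n_per background regions per foreground region (default 2).
#' @param seed RNG seed.
#' @param max_tries rejection-sampling cap per region.
#' @return interval table of background regions.
#' @export
matched_background <- function(foreground, chrom_lengths, n_per = 2,
                               seed = 1, max_tries = 50) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(foreground))) {
    w <- foreground$end[i] - foreground$start[i]
    chrom <- foreground$chrom[i]
    len <- chrom_lengths[[chrom]]
    got <- 0
    for (tr in seq_len(max_tries)) {
      if (got >= n_per) break
      s <- floor(stats::runif(1, 0, len - w))
      cand <- data.frame(chrom = chrom, start = s, end = s + w)
      if (nrow(overlap_query(cand, foreground)) == 0) {
        out[[length(out) + 1]] <- cand
        got <- got + 1
      }
    }
  }
  if (!length(out)) return(intervals(character(0), numeric(0), numeric(0)))
  res <- do.call(rbind, out)
  sort_intervals(intervals(res$chrom, res$start, res$end))
}
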