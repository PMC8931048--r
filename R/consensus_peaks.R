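#' Multi-replicate consensus peak calling
#'
#' Implements the double-threshold consensus scheme used for multi-replicate
#' ChIP/ATAC peak sets: peaks weaker than the *weak* threshold are discarded
#' outright; surviving peaks borrow evidence from overlapping peaks in the
#' other replicates through Fisher's combined probability, and are confirmed
#' when the combined evidence beats the *stringent* threshold with enough
#' replicate support (or when the peak is stringent on its own). Confirmed
#' peaks that overlap are merged by union.
#'
#' @details
#' For a peak with own p-value and one supporter chosen per other replicate
#' (the lowest-p overlapping peak, when several overlap), the Fisher
#' statistic is \eqn{X^2 = -2 \sum \ln p} over the peak and its supporters,
#' referred to a chi-square distribution with \eqn{2r} degrees of freedom
#' (\eqn{r} = number of combined peaks). A peak is confirmed if
#' `combined_p < stringent` and its supporter count + 1 >= `min_support`,
#' or if its own p `< stringent`.
#'
#' @param peak_sets list of interval tables (one per replicate) carrying a
#'   `pvalue` column.
#' @param weak weak threshold (default 1e-4): peaks at or above it are
#'   discarded before combination.
#' @param stringent stringent threshold (default 1e-8).
#' @param min_support minimum number of replicates (the peak itself plus
#'   supporters) required for confirmation by combined evidence; default
#'   majority, `ceiling(R / 2)`.
#' @param mode "narrow" or "broad"; metadata only (broad marks are called
#'   broad upstream), the consensus arithmetic is identical.
#' @return data.frame of class `consensus_peaks` with columns chrom, start,
#'   end, combined_p, support, n_members.
#' @export
combine_replicates <- function(peak_sets, weak = 1e-4, stringent = 1e-8,
                               min_support = NULL,
                               mode = c("narrow", "broad")) {
  mode <- match.arg(mode)
  if (!is.list(peak_sets) || length(peak_sets) == 0)
    abort_validation("peak_sets must be a non-empty list of interval tables")
  R <- length(peak_sets)
  if (is.null(min_support)) min_support <- ceiling(R / 2)
  if (!(stringent > 0 && stringent <= weak && weak < 1))
    abort_validation("need 0 < stringent <= weak < 1")

  pool <- do.call(rbind, lapply(seq_len(R), function(r) {
    x <- peak_sets[[r]]
    if (nrow(x) && any(!is.na(x$pvalue) & x$pvalue == 0)) {
      warning("p-value of 0 clamped to smallest positive double")
      x$pvalue[!is.na(x$pvalue) & x$pvalue == 0] <- .Machine$double.xmin
    }
    validate_intervals(x)
    if (nrow(x) && any(is.na(x$pvalue)))
      abort_validation("replicate %d has peaks without p-values", r)
    if (nrow(x) == 0) return(NULL)
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               pvalue = x$pvalue, replicate = r, source_row = seq_len(nrow(x)))
  }))
  empty <- {
    z <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), combined_p = numeric(0),
                    support = integer(0), n_members = integer(0))
    class(z) <- c("consensus_peaks", "data.frame"); z
  }
  if (is.null(pool) || nrow(pool) == 0) return(empty)
  pool <- pool[pool$pvalue < weak, , drop = FALSE]
  if (nrow(pool) == 0) return(empty)
  rownames(pool) <- NULL

  # best (lowest-p) overlapping supporter per other replicate
  hits <- overlap_query(pool, pool, min_bp = 1)
  hits <- hits[pool$replicate[hits$query] != pool$replicate[hits$subject], ,
               drop = FALSE]
  n <- nrow(pool)
  logp_sum <- log(pool$pvalue)      # own contribution
  n_comb <- rep(1L, n)
  if (nrow(hits)) {
    key <- paste(hits$query, pool$replicate[hits$subject])
    ord <- order(hits$query, pool$replicate[hits$subject],
                 pool$pvalue[hits$subject])
    hits <- hits[ord, , drop = FALSE]
    best <- hits[!duplicated(paste(hits$query,
                                   pool$replicate[hits$subject])), ,
                 drop = FALSE]
    add <- tapply(log(pool$pvalue[best$subject]), best$query, sum)
    cnt <- tapply(best$subject, best$query, length)
    idx <- as.integer(names(add))
    logp_sum[idx] <- logp_sum[idx] + as.numeric(add)
    n_comb[idx] <- n_comb[idx] + as.integer(cnt)
  }
  x2 <- -2 * logp_sum
  combined_p <- stats::pchisq(x2, df = 2 * n_comb, lower.tail = FALSE)
  confirmed <- (combined_p < stringent & n_comb >= min_support) |
    (pool$pvalue < stringent)
  if (!any(confirmed)) return(empty)

  conf <- pool[confirmed, , drop = FALSE]
  conf$combined_p <- combined_p[confirmed]
  # merge mutually overlapping confirmed peaks by union
  merged <- reduce_intervals(conf)
  memb <- overlap_query(conf, merged, min_bp = 1)
  out <- merged
  out$combined_p <- as.numeric(
    tapply(conf$combined_p[memb$query], memb$subject, min)[
      as.character(seq_len(nrow(merged)))])
  out$support <- as.integer(
    tapply(conf$replicate[memb$query], memb$subject,
           function(r) length(unique(r)))[as.character(seq_len(nrow(merged)))])
  out$n_members <- as.integer(
    tapply(memb$query, memb$subject, length)[
      as.character(seq_len(nrow(merged)))])
  out <- out[, c("chrom", "start", "end", "combined_p", "support",
                 "n_members")]
  attr(out, "members") <- split(
    conf[memb$query, c("replicate", "source_row")], memb$subject)
  attr(out, "mode") <- mode
  class(out) <- c("consensus_peaks", "data.frame")
  out
}

#' Write consensus peaks as BED6+ (combined_p, support)
#' @param x `consensus_peaks` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(x, path) {
  lines <- sprintf("%s\t%.0f\t%.0f\tconsensus_%d\t0\t*\t%.6g\t%d",
                   x$chrom, x$start, x$end, seq_len(nrow(x)),
                   x$combined_p, x$support)
  writeLines(lines, path)
  invisible(path)
}

#' Read consensus peaks written by [write_consensus()]
#' @param path input path.
#' @return `consensus_peaks` table.
#' @export
read_consensus <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(chrom = x[[1]], start = as.numeric(x[[2]]),
                    end = as.numeric(x[[3]]), combined_p = as.numeric(x[[7]]),
                    support = as.integer(x[[8]]),
                    n_members = NA_integer_)
  class(out) <- c("consensus_peaks", "data.frame")
  out
}
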