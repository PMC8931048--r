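#' Genomic coordinate conventions
#'
#' All intervals in this package are 0-based, half-open `[start, end)` (the
#' BED convention), on unstranded linear coordinates. Strand enters only when
#' a transcription start site (TSS) is derived from a gene model; interval
#' arithmetic itself never consults strand. GFF input (1-based, closed) is
#' converted on read.
#'
#' @name coordinate-conventions
NULL

#' Construct a genome layout
#'
#' A `genome_layout` records chromosome names, lengths and the bin width used
#' for chromatin-state segmentation. Bin count per chromosome is
#' `ceiling(length / bin_width)`.
#'
#' @param chrom_names character vector of chromosome identifiers (ordered).
#' @param chrom_lengths integer vector of chromosome lengths in bp.
#' @param bin_width bin width in bp (default 200, the segmentation
#'   convention for histone-mark binarization).
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chrom_names, chrom_lengths, bin_width = 200) {
  if (length(chrom_names) != length(chrom_lengths))
    abort_validation("chrom_names and chrom_lengths differ in length")
  if (any(duplicated(chrom_names)))
    abort_validation("duplicated chromosome names")
  if (any(chrom_lengths <= 0) || bin_width <= 0)
    abort_validation("chromosome lengths and bin_width must be > 0")
  n_bins <- as.integer(ceiling(chrom_lengths / bin_width))
  structure(list(
    chrom_names   = as.character(chrom_names),
    chrom_lengths = stats::setNames(as.numeric(chrom_lengths), chrom_names),
    bin_width     = as.numeric(bin_width),
    n_bins        = stats::setNames(n_bins, chrom_names),
    # 0-based global bin offset of each chromosome's first bin
    bin_offsets   = stats::setNames(c(0L, cumsum(n_bins))[seq_along(n_bins)],
                                    chrom_names)
  ), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_names), "chromosome(s),",
      sum(x$n_bins), "bins of", x$bin_width, "bp\n")
  invisible(x)
}

total_bins <- function(layout) sum(layout$n_bins)

#' Build a validated interval table
#'
#' @param chrom character chromosome names.
#' @param start,end 0-based half-open coordinates.
#' @param name,score,strand,pvalue optional per-interval annotation.
#' @param chrom_lengths optional named vector for bounds checking.
#' @return data.frame with class `intervals`.
#' @export
intervals <- function(chrom, start, end, name = NA_character_,
                      score = NA_real_, strand = "*", pvalue = NA_real_,
                      chrom_lengths = NULL) {
  n <- length(chrom)
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), name = rep_len(name, n),
                  score = rep_len(score, n), strand = rep_len(strand, n),
                  pvalue = rep_len(pvalue, n),
                  stringsAsFactors = FALSE)
  validate_intervals(x, chrom_lengths)
  class(x) <- c("intervals", "data.frame")
  x
}

#' Validate an interval table
#'
#' @param x data.frame with at least chrom/start/end.
#' @param chrom_lengths optional named lengths for bounds checking.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, chrom_lengths = NULL) {
  if (!all(c("chrom", "start", "end") %in% names(x)))
    abort_validation("interval table must have chrom, start, end columns")
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
    abort_validation("non-finite interval coordinates")
  if (any(x$start < 0)) abort_validation("negative start coordinate")
  bad <- which(x$start >= x$end)
  if (length(bad))
    abort_validation("start >= end at row %d (%s:%g-%g)", bad[1],
                     x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]])
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_lengths))
    if (length(unknown))
      abort_validation("unknown chromosome '%s'", unknown[1])
    over <- which(x$end > chrom_lengths[x$chrom])
    if (length(over))
      abort_validation("interval beyond chromosome end at row %d", over[1])
  }
  if ("pvalue" %in% names(x)) {
    pv <- x$pvalue[!is.na(x$pvalue)]
    if (length(pv) && (any(pv <= 0) || any(pv > 1)))
      abort_validation("pvalue outside (0, 1]")
  }
  invisible(x)
}

#' Sort intervals by (chrom, start, end)
#' @param x interval table.
#' @return sorted interval table.
#' @export
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

# 0-based half-open -> GRanges (1-based closed), internal
as_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' All overlapping pairs between two interval sets
#'
#' Returns every pair `(query, subject)` on the same chromosome whose overlap
#' spans at least `min_bp` bases. Half-open adjacency (end == start) is not
#' an overlap.
#'
#' @param a,b interval tables.
#' @param min_bp minimum overlap in bp (>= 1).
#' @return data.frame with integer columns `query`, `subject` (row indices
#'   into `a` and `b`).
#' @export
overlap_query <- function(a, b, min_bp = 1) {
  if (min_bp < 1) abort_validation("min_bp must be >= 1")
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(query = integer(0), subject = integer(0)))
  # seqlevel mismatches between the two sets are routine, not a problem
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_gr(a), as_gr(b),
                                minoverlap = as.integer(min_bp)))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

# bp length of the overlap of each pair, internal
overlap_widths <- function(a, b, pairs) {
  pmin(a$end[pairs$query], b$end[pairs$subject]) -
    pmax(a$start[pairs$query], b$start[pairs$subject])
}

#' Merge overlapping intervals into their union
#' @param x interval table.
#' @return interval table of disjoint unions, sorted.
#' @export
reduce_intervals <- function(x) {
  if (nrow(x) == 0) return(intervals(character(0), numeric(0), numeric(0)))
  # min.gapwidth = 0: merge overlapping ranges only -- half-open adjacency
  # is not an overlap
  r <- GenomicRanges::reduce(as_gr(x), min.gapwidth = 0L)
  intervals(as.character(GenomicRanges::seqnames(r)),
            GenomicRanges::start(r) - 1, GenomicRanges::end(r))
}

#' Read a BED-family file
#'
#' Supports plain BED3/BED6 and a narrowPeak-like dialect
#' (chrom, start, end, name, score, strand, signal, -log10 p), in which the
#' eighth column is converted to `pvalue = 10^(-col)`.
#'
#' @param path file path.
#' @param dialect one of "bed3", "bed6", "narrowPeak".
#' @return sorted interval table.
#' @export
read_bed <- function(path, dialect = c("bed3", "bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_validation("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(intervals(character(0), numeric(0), numeric(0)))
  need <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 8L)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  short <- which(nf < need)
  if (length(short))
    abort_parse("%s line %d: expected >= %d tab-separated fields, got %d",
                path, short[1], need, nf[short[1]])
  get <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    abort_parse("%s line %d: coordinates do not parse as non-negative integers",
                path, bad[1])
  badord <- which(start >= end)
  if (length(badord))
    abort_validation("%s line %d: start >= end", path, badord[1])
  x <- data.frame(chrom = get(1), start = start, end = end,
                  stringsAsFactors = FALSE)
  if (dialect != "bed3") {
    x$name <- get(4)
    x$score <- suppressWarnings(as.numeric(get(5)))
    x$strand <- get(6)
  } else {
    x$name <- NA_character_; x$score <- NA_real_; x$strand <- "*"
  }
  x$pvalue <- if (dialect == "narrowPeak") {
    mlp <- suppressWarnings(as.numeric(get(8)))
    badp <- which(is.na(mlp))
    if (length(badp))
      abort_parse("%s line %d: -log10(p) column does not parse", path, badp[1])
    10^(-mlp)
  } else NA_real_
  x <- sort_intervals(x)
  rownames(x) <- NULL
  class(x) <- c("intervals", "data.frame")
  x
}

#' Write a BED-family file
#'
#' Emits sorted, tab-separated, newline-terminated records.
#'
#' @param x interval table.
#' @param path output path.
#' @param dialect one of "bed3", "bed6", "narrowPeak".
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, dialect = c("bed3", "bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  x <- sort_intervals(x)
  fmt_int <- function(v) sprintf("%.0f", v)
  cols <- list(x$chrom, fmt_int(x$start), fmt_int(x$end))
  if (dialect != "bed3") {
    nm <- ifelse(is.na(x$name), ".", x$name)
    sc <- ifelse(is.na(x$score), "0", format(x$score, trim = TRUE))
    st <- ifelse(is.na(x$strand) | x$strand == "", "*", x$strand)
    cols <- c(cols, list(nm, sc, st))
  }
  if (dialect == "narrowPeak") {
    sig <- ifelse(is.na(x$score), "0", format(x$score, trim = TRUE))
    mlp <- ifelse(is.na(x$pvalue), "-1", sprintf("%.6g", -log10(x$pvalue)))
    cols <- c(cols, list(sig, mlp))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Build a gene-model table
#'
#' The TSS is `start` on the + strand and `end - 1` on the - strand (the
#' last covered base of the half-open body).
#'
#' @param gene_id identifiers (unique).
#' @param chrom chromosome per gene.
#' @param strand "+" or "-".
#' @param start,end gene body, 0-based half-open.
#' @return data.frame with class `gene_models` and a `tss` column.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end) {
  if (any(duplicated(gene_id))) abort_validation("duplicated gene_id")
  if (!all(strand %in% c("+", "-")))
    abort_validation("strand must be '+' or '-'")
  if (any(start >= end)) abort_validation("gene body start >= end")
  g <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  strand = strand, start = as.numeric(start),
                  end = as.numeric(end), stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  class(g) <- c("gene_models", "data.frame")
  g
}

#' Promoter windows around gene TSS
#'
#' Returns `[tss - flank, tss + flank)` per gene, clipped to chromosome
#' bounds when `chrom_lengths` is given. Strand-independent by design.
#'
#' @param genes gene-model table.
#' @param flank half-width in bp (default 2000).
#' @param chrom_lengths optional named chromosome lengths for clipping.
#' @return interval table with `name` = gene_id, in gene order.
#' @export
promoter_window <- function(genes, flank = 2000, chrom_lengths = NULL) {
  if (flank <= 0) abort_validation("flank must be > 0")
  start <- pmax(genes$tss - flank, 0)
  end <- genes$tss + flank
  if (!is.null(chrom_lengths)) {
    lens <- chrom_lengths[genes$chrom]
    end <- pmin(end, lens)
  }
  intervals(genes$chrom, start, end, name = genes$gene_id,
            strand = genes$strand)
}

#' Validate a TAD set
#'
#' TADs must be sorted and pairwise disjoint within each chromosome.
#'
#' @param tads interval table.
#' @return `tads` sorted, with class `tad_set`.
#' @export
tad_set <- function(tads) {
  validate_intervals(tads)
  tads <- sort_intervals(tads)
  by_chrom <- split(seq_len(nrow(tads)), tads$chrom)
  for (idx in by_chrom) {
    if (length(idx) > 1) {
      s <- tads$start[idx]; e <- tads$end[idx]
      if (any(s[-1] < e[-length(e)]))
        abort_validation("overlapping TADs on %s", tads$chrom[idx[1]])
    }
  }
  rownames(tads) <- NULL
  class(tads) <- c("tad_set", "intervals", "data.frame")
  tads
}

# Index of the TAD containing each (chrom, pos) point; NA when outside all
# TADs. Disjointness makes the lookup unambiguous.
locate_in_tads <- function(chrom, pos, tads) {
  pts <- data.frame(chrom = chrom, start = pos, end = pos + 1)
  hits <- overlap_query(pts, tads, min_bp = 1)
  out <- rep(NA_integer_, length(pos))
  out[hits$query] <- hits$subject
  out
}

#' Read gene models from GFF3 (gene features only)
#'
#' GFF3 is 1-based closed; coordinates are converted to the package's
#' 0-based half-open convention on read. The `ID` attribute names the gene.
#'
#' @param path GFF3 file.
#' @return `gene_models` table.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene", NA)
  fields <- fields[keep]
  if (!length(fields))
    return(gene_models(character(0), character(0), character(0),
                       numeric(0), numeric(0)))
  get <- function(i) vapply(fields, `[[`, "", i)
  ids <- sub(".*ID=([^;]+).*", "\\1", get(9))
  start1 <- suppressWarnings(as.numeric(get(4)))
  end1 <- suppressWarnings(as.numeric(get(5)))
  if (any(is.na(start1)) || any(is.na(end1)))
    abort_parse("%s: gene coordinates do not parse", path)
  gene_models(ids, get(1), get(7), start1 - 1, end1)
}

#' Write gene models as GFF3 gene features
#' @param genes `gene_models` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  lines <- sprintf("%s\tepicmml\tgene\t%.0f\t%.0f\t.\t%s\t.\tID=%s",
                   genes$chrom, genes$start + 1, genes$end, genes$strand,
                   genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
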