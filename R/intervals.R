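# Genomic intervals are plain data.frames in BED convention: 0-based,
# half-open [start, end).  Conversion to GRanges (1-based, closed) happens
# only inside the overlap helpers, so every user-facing coordinate follows
# the single internal convention.

#' Construct a genomic interval table
#'
#' Intervals are stored as a plain `data.frame` with columns `chrom`,
#' `start`, `end`, `name`, `strand`, using the BED convention: 0-based,
#' half-open `[start, end)`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start >= 0`, `end > start`.
#' @param name optional interval names (recycled).
#' @param strand optional strand in `+`, `-` or `.` (recycled).
#' @return a `data.frame` of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              strand = ".") {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  name = as.character(name),
                  strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

validate_intervals <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start < 0)) stop("interval start must be >= 0")
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    stop(sprintf("interval end must exceed start (row %d: [%d, %d))",
                 bad, x$start[bad], x$end[bad]))
  }
  invisible(x)
}

#' @keywords internal
intervals_to_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "."
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(seqnames = x$chrom,
                         ranges = IRanges::IRanges(start = x$start + 1L,
                                                   end = x$end),
                         strand = strand)
}

#' Overlap queries between two interval tables
#'
#' Overlap means at least one shared base pair.
#'
#' @param query,subject interval `data.frame`s (`chrom`, `start`, `end`).
#' @return `overlaps_any()`: logical vector along `query` rows.
#'   `overlap_pairs()`: `data.frame` with columns `query`, `subject`
#'   holding row indices of every overlapping pair.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(query),
                                      intervals_to_granges(subject),
                                      ignore.strand = TRUE)
  seq_len(nrow(query)) %in% S4Vectors::queryHits(hits)
}

#' @rdname overlaps_any
#' @export
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(query),
                                      intervals_to_granges(subject),
                                      ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

# Strand-aware anchored windows.  For a plus-strand gene the promoter is
# [tss - upstream, tss + downstream); for a minus-strand gene the interval
# is the exact mirror image about the TSS base, so both strands give a
# window of identical length with the same orientation relative to
# transcription.
anchored_window <- function(anchor, strand, upstream, downstream) {
  plus <- strand != "-"
  start <- ifelse(plus, anchor - upstream, anchor - downstream + 1L)
  end <- ifelse(plus, anchor + downstream, anchor + upstream + 1L)
  data.frame(start = as.integer(pmax(start, 0L)), end = as.integer(end))
}

#' Promoter and gene-body intervals from gene models
#'
#' Promoters span 1 kb upstream of the TSS to 500 bp downstream of the TSS;
#' gene bodies run from 500 bp downstream of the TSS to the transcription
#' termination site.  Both are oriented by strand.
#'
#' @param genes gene-model `data.frame` with columns `gene_id`, `chrom`,
#'   `strand`, `tss`, `tts` (0-based base coordinates).
#' @param upstream,downstream promoter extent in bp around the TSS.
#' @return interval table with `name` set to `gene_id`.
#' @export
gene_promoters <- function(genes, upstream = 1000L, downstream = 500L) {
  w <- anchored_window(genes$tss, genes$strand, upstream, downstream)
  genomic_intervals(genes$chrom, w$start, w$end, name = genes$gene_id,
                    strand = genes$strand)
}

#' @rdname gene_promoters
#' @param tss_offset bp downstream of the TSS where the gene body starts.
#' @export
gene_bodies <- function(genes, tss_offset = 500L) {
  plus <- genes$strand != "-"
  start <- ifelse(plus, genes$tss + tss_offset, genes$tts)
  end <- ifelse(plus, genes$tts, genes$tss - tss_offset + 1L)
  keep <- end > start
  if (!all(keep)) {
    warning(sprintf("%d gene(s) shorter than the TSS offset dropped from gene bodies",
                    sum(!keep)))
  }
  g <- genes[keep, , drop = FALSE]
  genomic_intervals(g$chrom, start[keep], end[keep], name = g$gene_id,
                    strand = g$strand)
}
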