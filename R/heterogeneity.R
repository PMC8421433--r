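# Window-based methylation-variation scores over 4-CpG loci: Shannon
# entropy, Epipolymorphism and the proportion of discordant reads (PDR).
# A locus is a window of 4 adjacent CpGs in genomic order; only reads with
# non-missing calls at all four CpGs support it, so these scores by
# construction use fewer reads than the concurrence ratio, which has no
# per-read CpG-count requirement.

LOCUS_SIZE <- 4L

#' Enumerate 4-CpG epiallele tables
#'
#' Slides a window over every 4 adjacent CpGs of the observed CpG map and
#' tabulates the epiallele (joint methylation pattern) counts of reads that
#' cover all four CpGs with non-missing calls.  Windows supported by fewer
#' than `coverage_min` such reads are dropped.
#'
#' @inheritParams concurrence_track
#' @param region optional single-row interval table; keeps loci whose first
#'   CpG lies inside the region.
#' @return `data.frame` with `chrom`, `start_pos` (first CpG), a
#'   `positions` list column, `total` reads, and a `counts` list column of
#'   named pattern counts (names are 4-character strings over `{0,1}`).
#'   Attribute `"n_reads_eligible"` counts reads with >= 4 non-missing
#'   calls (the reads the scores can ever use).
#' @export
enumerate_loci <- function(records, region = NULL, coverage_min = 4L) {
  ob <- obs_table(records)
  eligible <- sum(tapply(rep(1L, nrow(ob)), ob$read, sum) >= LOCUS_SIZE)
  out <- list()
  for (chr in unique(ob$chrom)) {
    oc <- ob[ob$chrom == chr, , drop = FALSE]
    sites <- sort(unique(oc$pos))
    if (length(sites) < LOCUS_SIZE) next
    for (w in seq_len(length(sites) - LOCUS_SIZE + 1L)) {
      wpos <- sites[w:(w + LOCUS_SIZE - 1L)]
      if (!is.null(region)) {
        if (chr != region$chrom || wpos[1] < region$start ||
            wpos[1] >= region$end) next
      }
      ow <- oc[oc$pos %in% wpos, , drop = FALSE]
      full <- names(which(table(ow$read) == LOCUS_SIZE))
      if (length(full) < coverage_min) next
      ow <- ow[ow$read %in% as.integer(full), , drop = FALSE]
      ow <- ow[order(ow$read, ow$pos), , drop = FALSE]
      pat <- vapply(split(ow$call, ow$read), paste, character(1),
                    collapse = "")
      counts <- table(pat)
      out[[length(out) + 1L]] <- list(chrom = chr, start_pos = wpos[1],
                                      positions = wpos,
                                      total = length(pat),
                                      counts = counts)
    }
  }
  res <- data.frame(
    chrom = vapply(out, `[[`, character(1), "chrom"),
    start_pos = vapply(out, `[[`, integer(1), "start_pos"),
    total = vapply(out, `[[`, integer(1), "total"),
    stringsAsFactors = FALSE)
  res$positions <- lapply(out, `[[`, "positions")
  res$counts <- lapply(out, function(x) {
    v <- as.integer(x$counts)
    names(v) <- names(x$counts)
    v
  })
  attr(res, "n_reads_eligible") <- eligible
  res
}

#' Shannon entropy of an epiallele table
#'
#' `-sum(p_i * log(p_i))` over observed patterns.  The default base 2 gives
#' the documented 0-4 range for 16 possible 4-CpG patterns (the natural-log
#' variant is available via `log_base = exp(1)`).
#'
#' @param counts named integer vector of pattern counts.
#' @param log_base logarithm base (2 or `exp(1)`).
#' @return entropy in `[0, 4]` for base 2.
#' @export
methylation_entropy <- function(counts, log_base = 2) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = log_base))
}

#' Epipolymorphism of an epiallele table
#'
#' `1 - sum(p_i^2)`; ranges from 0 (single pattern) to 15/16 (uniform over
#' the 16 patterns).
#'
#' @inheritParams methylation_entropy
#' @export
epipolymorphism <- function(counts) {
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Proportion of discordant reads of an epiallele table
#'
#' The fraction of reads whose 4 calls contain both a 0 and a 1.
#'
#' @inheritParams methylation_entropy
#' @export
pdr <- function(counts) {
  disc <- grepl("0", names(counts)) & grepl("1", names(counts))
  sum(counts[disc]) / sum(counts)
}

#' Region-level heterogeneity scores
#'
#' The entropy, Epipolymorphism and PDR of a region are the unweighted
#' means of the per-locus scores over 4-CpG loci whose first CpG lies in
#' the region.
#'
#' @inheritParams enumerate_loci
#' @param log_base entropy logarithm base.
#' @return list with `entropy`, `epipolymorphism`, `pdr`, `n_loci`; all
#'   scores `NA` when no locus qualifies.
#' @export
region_heterogeneity <- function(records, region = NULL,
                                 coverage_min = 4L, log_base = 2) {
  loci <- enumerate_loci(records, region, coverage_min)
  if (nrow(loci) == 0L) {
    return(list(entropy = NA_real_, epipolymorphism = NA_real_,
                pdr = NA_real_, n_loci = 0L))
  }
  list(entropy = mean(vapply(loci$counts, methylation_entropy,
                             numeric(1), log_base = log_base)),
       epipolymorphism = mean(vapply(loci$counts, epipolymorphism,
                                     numeric(1))),
       pdr = mean(vapply(loci$counts, pdr, numeric(1))),
       n_loci = nrow(loci))
}
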