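# Canyon and gene annotation statistics: TSS-anchored binned
# methylation-expression correlation, motif counts-per-kilobase fold
# enrichment between canyon classes, transcription-factor occupancy
# ratios, and chromatin-interaction classification with length-matched
# shuffle controls.

N_BINS <- 120L
BIN_BP <- 100L
BIN_UPSTREAM <- 2000L

#' TSS-anchored binned methylation matrix
#'
#' For every gene, the window from 2 kb upstream to 10 kb downstream of
#' the TSS is divided into 120 bins of 100 bp, oriented by strand (bin 1
#' is the most upstream).  A bin's value is the coverage-weighted mean
#' methylation (`sum(n_meth)/sum(n_reads)`) over its qualifying CpGs, `NA`
#' when the bin holds none.
#'
#' @param track a [meth_track()] result (columns `chrom`, `pos`,
#'   `n_reads`, `n_meth`).
#' @param genes gene-model `data.frame`.
#' @return numeric matrix, genes x 120 bins, rownames = `gene_id`.
#' @export
binned_matrix <- function(track, genes) {
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = N_BINS,
              dimnames = list(genes$gene_id, NULL))
  span <- N_BINS * BIN_BP
  for (i in seq_len(nrow(genes))) {
    t0 <- genes$tss[i]
    plus <- genes$strand[i] != "-"
    lo <- if (plus) t0 - BIN_UPSTREAM else t0 - (span - BIN_UPSTREAM) + 1L
    tc <- track[track$chrom == genes$chrom[i] & track$pos >= lo &
                  track$pos < lo + span, , drop = FALSE]
    if (nrow(tc) == 0L) next
    off <- tc$pos - lo
    bin <- if (plus) off %/% BIN_BP + 1L else
      N_BINS - off %/% BIN_BP
    nm <- rowsum(tc$n_meth, bin)
    nr <- rowsum(tc$n_reads, bin)
    m[i, as.integer(rownames(nm))] <- nm / nr
  }
  m
}

#' Per-bin correlation with expression
#'
#' Spearman rank correlation between the expression vector and each column
#' of the binned methylation matrix, over genes with non-missing values in
#' that bin.
#'
#' @param matrix a [binned_matrix()] result.
#' @param expression named numeric vector of expression values.
#' @param method correlation method (default `"spearman"`).
#' @param min_genes minimum genes with data per bin (default 10); bins
#'   below the floor, or with a constant methylation vector, give `NA`.
#' @return numeric vector of 120 coefficients.
#' @export
per_bin_correlation <- function(matrix, expression, method = "spearman",
                                min_genes = 10L) {
  common <- intersect(rownames(matrix), names(expression))
  m <- matrix[common, , drop = FALSE]
  e <- expression[common]
  apply(m, 2, function(col) {
    ok <- !is.na(col)
    if (sum(ok) < min_genes || stats::sd(col[ok]) == 0 ||
        stats::sd(e[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(col[ok], e[ok], method = method)
  })
}

#' Motif counts per kilobase of a region set
#'
#' A hit belongs to a region when its midpoint lies inside it (so a hit is
#' never double-counted across a region border).
#'
#' @param hits interval table of motif hits.
#' @param regions interval table; total length must be positive.
#' @return hits per kb of total region length.
#' @export
cpk <- function(hits, regions) {
  total_kb <- sum(regions$end - regions$start) / 1000
  if (total_kb <= 0) stop("zero-length region set")
  if (nrow(hits) == 0L) return(0)
  mid <- (hits$start + hits$end) %/% 2L
  midpoints <- genomic_intervals(hits$chrom, mid, mid + 1L)
  sum(overlaps_any(midpoints, regions)) / total_kb
}

#' Motif fold enrichment between canyon classes
#'
#' For each motif, the log2 fold change between its CPK in aCanyons and in
#' pCanyons, compared against an external 5mC-preference value per motif
#' (positive = methyl-plus).  When either CPK is zero, one pseudo-hit is
#' added to both counts and the motif is flagged.
#'
#' @param hits_by_motif named list of hit interval tables, one per motif.
#' @param acanyons,pcanyons canyon interval tables.
#' @param preferences named numeric vector of 5mC preferences per motif.
#' @return list with `table` (per-motif `cpk_a`, `cpk_p`, `log2_fold`,
#'   `preference`, `class`, `pseudocount`) and `correlation` (the
#'   rank-correlation test of fold vs preference).
#' @export
motif_fold_enrichment <- function(hits_by_motif, acanyons, pcanyons,
                                  preferences) {
  kb_a <- sum(acanyons$end - acanyons$start) / 1000
  kb_p <- sum(pcanyons$end - pcanyons$start) / 1000
  motifs <- names(hits_by_motif)
  rows <- lapply(motifs, function(m) {
    ca <- cpk(hits_by_motif[[m]], acanyons) * kb_a   # back to counts
    cp <- cpk(hits_by_motif[[m]], pcanyons) * kb_p
    pseudo <- ca == 0 || cp == 0
    if (pseudo) {
      ca <- ca + 1
      cp <- cp + 1
    }
    cpk_a <- ca / kb_a
    cpk_p <- cp / kb_p
    data.frame(motif = m, cpk_a = cpk_a, cpk_p = cpk_p,
               log2_fold = log2(cpk_a / cpk_p),
               preference = unname(preferences[m]),
               class = if (is.na(preferences[m])) NA_character_ else
                 if (preferences[m] > 0) "methyl-plus" else "methyl-minus",
               pseudocount = pseudo, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$log2_fold) & is.finite(tab$preference)
  corr <- if (sum(ok) >= 3L) {
    ct <- suppressWarnings(
      stats::cor.test(tab$log2_fold[ok], tab$preference[ok],
                      method = "spearman", alternative = "two.sided"))
    list(rho = unname(ct$estimate), p_value = ct$p.value)
  } else {
    list(rho = NA_real_, p_value = NA_real_)
  }
  list(table = tab, correlation = corr)
}

#' TF occupancy ratio between canyon classes
#'
#' The fraction of aCanyons overlapping at least one binding peak divided
#' by the same fraction for pCanyons (the "odds ratio" of the canyon
#' occupancy percentages; a ratio of proportions).  `Inf` when no pCanyon
#' is occupied.
#'
#' @param peaks interval table of TF binding peaks.
#' @param acanyons,pcanyons canyon interval tables (both non-empty).
#' @return the occupancy ratio.
#' @export
tf_odds_ratio <- function(peaks, acanyons, pcanyons) {
  stopifnot(nrow(acanyons) > 0, nrow(pcanyons) > 0)
  fa <- mean(overlaps_any(acanyons, peaks))
  fp <- mean(overlaps_any(pcanyons, peaks))
  if (fp == 0) return(Inf)
  fa / fp
}

#' Classify chromatin-interaction anchor pairs against regions
#'
#' `self-interacting`: both anchors overlap the same region;
#' `distant-interacting`: at least one anchor overlaps a region but not
#' both the same one (this includes pairs spanning two different regions);
#' `none`: neither anchor overlaps any region.
#'
#' @param pairs list with row-aligned interval tables `anchor1`,
#'   `anchor2` (as from [read_anchor_pairs()]).
#' @param regions interval table (canyons or shuffled controls).
#' @return character vector of labels along the pairs.
#' @export
classify_interactions <- function(pairs, regions) {
  h1 <- overlap_pairs(pairs$anchor1, regions)
  h2 <- overlap_pairs(pairs$anchor2, regions)
  n <- nrow(pairs$anchor1)
  vapply(seq_len(n), function(i) {
    r1 <- h1$subject[h1$query == i]
    r2 <- h2$subject[h2$query == i]
    if (length(intersect(r1, r2)) > 0) "self-interacting"
    else if (length(r1) > 0 || length(r2) > 0) "distant-interacting"
    else "none"
  }, character(1))
}

#' Length-matched shuffled control regions
#'
#' Generates one random region per input region with exactly the same
#' length, mutually non-overlapping, placed uniformly on the genome.
#'
#' @param regions interval table to match lengths against.
#' @param chrom_sizes named numeric vector of chromosome sizes.
#' @param seed optional integer seed.
#' @return interval table of shuffled regions (same length multiset).
#' @export
shuffle_regions <- function(regions, chrom_sizes, seed = NULL) {
  with_seed(seed,
            place_nonoverlapping(chrom_sizes,
                                 as.integer(regions$end - regions$start)))
}
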