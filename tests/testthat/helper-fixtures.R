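# Fixture builders and independent oracles used across the suite.

# Reads sharing one set of CpG positions, given as call strings over
# {0,1,?}.
shared_reads <- function(callstrings, positions = NULL, chrom = "chr1") {
  k <- nchar(callstrings[1])
  if (is.null(positions)) positions <- seq(100L, by = 10L,
                                           length.out = k)
  calls <- lapply(strsplit(callstrings, ""), function(s) {
    v <- rep(NA_integer_, length(s))
    v[s == "1"] <- 1L
    v[s == "0"] <- 0L
    v
  })
  epireads(chrom, sprintf("r%d", seq_along(callstrings)),
           rep(list(positions), length(callstrings)), calls)
}

# Random small read set over a shared site grid (no missing calls).
random_readset <- function(n_reads, n_sites = 8L, k_range = 2:6) {
  sites <- sort(sample.int(1000L, n_sites)) + 100L
  pos <- list(); calls <- list()
  for (i in seq_len(n_reads)) {
    k <- min(sample(k_range, 1L), n_sites)
    s <- sample.int(n_sites - k + 1L, 1L)
    pos[[i]] <- sites[s:(s + k - 1L)]
    repeat {
      v <- sample(0:1, k, replace = TRUE)
      if (TRUE) break
    }
    calls[[i]] <- as.integer(v)
  }
  epireads("chr1", sprintf("r%d", seq_len(n_reads)), pos, calls)
}

# Independent per-read oracle for the weighted concurrence ratio: walks
# every read with a plain loop, labels each non-missing call from the
# whole-read state, and counts C labels over qualifying in-region
# observations.  Deliberately avoids dissect_read/obs_table.
oracle_concurrence <- function(records, region = NULL,
                               coverage_min = 1L) {
  cov <- list()
  for (i in seq_len(nrow(records))) {
    keep <- !is.na(records$calls[[i]])
    for (p in records$positions[[i]][keep]) {
      key <- paste(records$chrom[i], p)
      cov[[key]] <- (cov[[key]] %||% 0L) + 1L
    }
  }
  n_c <- 0L; n_all <- 0L
  for (i in seq_len(nrow(records))) {
    keep <- !is.na(records$calls[[i]])
    v <- records$calls[[i]][keep]
    p <- records$positions[[i]][keep]
    mixed <- any(v == 1L) && any(v == 0L)
    for (j in seq_along(v)) {
      key <- paste(records$chrom[i], p[j])
      if (cov[[key]] < coverage_min) next
      if (!is.null(region)) {
        if (records$chrom[i] != region$chrom || p[j] < region$start ||
            p[j] >= region$end) next
      }
      n_all <- n_all + 1L
      if (mixed && v[j] == 0L) n_c <- n_c + 1L
    }
  }
  if (n_all == 0L) NA_real_ else n_c / n_all
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Eq.-1 fragment-sum route for the weighted ratio, built directly on
# dissect_read so it is an independent path from the per-CpG counting in
# concurrence_ratio.
fragment_sum_concurrence <- function(records, region = NULL,
                                     coverage_min = 1L) {
  cc <- cpg_counts(records)
  ok <- cc[cc$n_reads >= coverage_min, ]
  qualifies <- function(chrom, p) {
    inq <- any(ok$chrom == chrom & ok$pos == p)
    if (!inq) return(FALSE)
    is.null(region) || (chrom == region$chrom && p >= region$start &&
                          p < region$end)
  }
  w <- c(M = 0, U = 0, C = 0)
  for (i in seq_len(nrow(records))) {
    fr <- dissect_read(records$positions[[i]], records$calls[[i]])
    for (j in seq_len(nrow(fr))) {
      wt <- sum(vapply(fr$positions[[j]], qualifies, logical(1),
                       chrom = records$chrom[i]))
      w[fr$label[j]] <- w[fr$label[j]] + wt
    }
  }
  if (sum(w) == 0) NA_real_ else unname(w["C"] / sum(w))
}

single_region <- function(chrom, start, end) {
  genomic_intervals(chrom, start, end)
}
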