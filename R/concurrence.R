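# Read dissection and the methylation concurrence ratio.
#
# Every read is cut into maximal runs of equal methylation state over its
# non-missing calls: a fully methylated read is one M fragment, a fully
# unmethylated read is one U fragment, and a partially methylated read
# alternates M fragments (runs of 1s) with C fragments (runs of 0s) — the
# methylation-concurrence fragments, unmethylated CpGs that sit on the same
# molecule as methylated ones.  The concurrence ratio of a region is
# sum(w_C) / (sum(w_C) + sum(w_M) + sum(w_U)) with fragment weights w equal
# to the fragment's CpG count (weighted) or 1 (unweighted).  Weighted, this
# equals the proportion of C-labeled CpG observations among all CpG
# observations, which is why the ratio is also defined at a single CpG.
#
# Crucial convention: fragment labels come from the FULL read (a read is
# "partially methylated" or not as a molecule), while weights count only
# in-region CpGs that pass the coverage filter.

#' Dissect one read into M/U/C fragments
#'
#' @param positions strictly increasing CpG positions of one read.
#' @param calls integer calls over `{0, 1, NA}`; missing calls are skipped
#'   without breaking runs of equal state across them.
#' @return `data.frame` with one row per fragment: `label` in
#'   `{"M","U","C"}`, `n_cpgs` (the weight), and a `positions` list column
#'   of member CpGs.
#' @examples
#' dissect_read(c(100, 110, 120, 130), c(1L, 0L, 1L, 1L))
#' @export
dissect_read <- function(positions, calls) {
  keep <- !is.na(calls)
  if (!any(keep)) stop("all calls missing; cannot dissect read")
  p <- positions[keep]
  v <- calls[keep]
  r <- rle(v)
  lab <- if (all(v == 1L)) "M" else if (all(v == 0L)) "U" else
    ifelse(r$values == 1L, "M", "C")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(label = lab, n_cpgs = r$lengths,
                    stringsAsFactors = FALSE)
  out$positions <- lapply(seq_along(starts),
                          function(i) p[starts[i]:ends[i]])
  out
}

# Long observation table: one row per non-missing CpG call, with the
# per-observation fragment label and a fragment id unique within the table.
# This is the workhorse every region metric is computed from.
obs_table <- function(records) {
  n <- vapply(records$positions, length, integer(1))
  read <- rep.int(seq_len(nrow(records)), n)
  pos <- unlist(records$positions, use.names = FALSE)
  call <- unlist(records$calls, use.names = FALSE)
  chrom <- rep.int(records$chrom, n)
  keep <- !is.na(call)
  if (any(tapply(keep, read, sum) == 0L)) {
    stop("read with all calls missing")
  }
  read <- read[keep]; pos <- pos[keep]; call <- call[keep]
  chrom <- chrom[keep]
  # read class: 2 = mixed, 1 = fully methylated, 0 = fully unmethylated
  mx <- stats::ave(call, read, FUN = max)
  mn <- stats::ave(call, read, FUN = min)
  label <- character(length(call))
  label[mx == 0L] <- "U"
  label[mn == 1L] <- "M"
  mixed <- mx == 1L & mn == 0L
  label[mixed & call == 1L] <- "M"
  label[mixed & call == 0L] <- "C"
  newread <- c(TRUE, read[-1] != read[-length(read)])
  newfrag <- newread | c(TRUE, call[-1] != call[-length(call)])
  data.frame(chrom = chrom, pos = pos, read = read, call = call,
             label = label, frag = cumsum(newfrag),
             stringsAsFactors = FALSE)
}

#' Per-CpG observation counts
#'
#' Counts, for each CpG position, how many reads cover it, how many calls
#' are methylated, and how many observations carry each fragment label.
#'
#' @param records an [epireads] table.
#' @return `data.frame` with columns `chrom`, `pos`, `n_reads`, `n_meth`,
#'   `n_M`, `n_U`, `n_C` (one row per covered CpG, sorted).
#' @export
cpg_counts <- function(records) {
  ob <- obs_table(records)
  key <- paste(ob$chrom, ob$pos, sep = "\r")
  agg <- function(x) as.vector(rowsum(x, key))
  u <- !duplicated(key)
  out <- data.frame(chrom = ob$chrom[u], pos = ob$pos[u],
                    stringsAsFactors = FALSE)
  ord_key <- sort(unique(key))
  out <- out[order(paste(out$chrom, out$pos, sep = "\r")), , drop = FALSE]
  out$n_reads <- agg(rep(1L, nrow(ob)))
  out$n_meth <- agg(as.integer(ob$call == 1L))
  out$n_M <- agg(as.integer(ob$label == "M"))
  out$n_U <- agg(as.integer(ob$label == "U"))
  out$n_C <- agg(as.integer(ob$label == "C"))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-CpG methylation concurrence track
#'
#' The concurrence ratio at a single CpG: the proportion of reads covering
#' it in which it lies inside a methylation-concurrence fragment.  CpGs
#' covered by fewer than `coverage_min` reads are omitted.
#'
#' @inheritParams cpg_counts
#' @param coverage_min minimum read coverage per CpG (default 4).
#' @return `data.frame` with `chrom`, `pos`, `n_reads`, `value`.
#' @export
concurrence_track <- function(records, coverage_min = 4L) {
  cc <- cpg_counts(records)
  cc <- cc[cc$n_reads >= coverage_min, , drop = FALSE]
  data.frame(chrom = cc$chrom, pos = cc$pos, n_reads = cc$n_reads,
             value = cc$n_C / cc$n_reads, stringsAsFactors = FALSE)
}

#' Per-CpG mean methylation track
#'
#' @inheritParams concurrence_track
#' @return `data.frame` with `chrom`, `pos`, `n_reads`, `n_meth`, `value`.
#' @export
meth_track <- function(records, coverage_min = 4L) {
  cc <- cpg_counts(records)
  cc <- cc[cc$n_reads >= coverage_min, , drop = FALSE]
  data.frame(chrom = cc$chrom, pos = cc$pos, n_reads = cc$n_reads,
             n_meth = cc$n_meth, value = cc$n_meth / cc$n_reads,
             stringsAsFactors = FALSE)
}

# CpG positions (per chrom) passing the coverage filter.
qualifying_sites <- function(records, coverage_min) {
  cc <- cpg_counts(records)
  cc[cc$n_reads >= coverage_min, c("chrom", "pos")]
}

# Restrict an observation table to qualifying in-region observations.
restrict_obs <- function(ob, region, sites) {
  ok <- paste(ob$chrom, ob$pos) %in% paste(sites$chrom, sites$pos)
  if (!is.null(region)) {
    ok <- ok & ob$chrom == region$chrom & ob$pos >= region$start &
      ob$pos < region$end
  }
  ob[ok, , drop = FALSE]
}

#' Methylation concurrence ratio of a region
#'
#' Fragment labels are computed from the full read; weights count only the
#' fragment's CpGs that fall inside the region and pass the per-CpG
#' coverage filter.  Weighted, the ratio equals the proportion of C-labeled
#' observations; unweighted, each (clipped) fragment with at least one
#' qualifying in-region CpG counts once.
#'
#' @inheritParams concurrence_track
#' @param region single-row interval table, or `NULL` for all covered CpGs.
#' @param weighted use CpG-count weights (`TRUE`, default) or per-fragment
#'   weight 1 (`FALSE`).
#' @return ratio in `[0, 1)`, or `NA` if no qualifying CpG observation.
#' @export
concurrence_ratio <- function(records, region = NULL, weighted = TRUE,
                              coverage_min = 4L) {
  ob <- restrict_obs(obs_table(records), region,
                     qualifying_sites(records, coverage_min))
  if (nrow(ob) == 0L) return(NA_real_)
  if (weighted) {
    sum(ob$label == "C") / nrow(ob)
  } else {
    lab <- ob$label[!duplicated(ob$frag)]
    sum(lab == "C") / length(lab)
  }
}

#' Traditional mean methylation of a region
#'
#' The proportion of methylated CpG calls among all calls at qualifying
#' in-region CpGs.
#'
#' @inheritParams concurrence_ratio
#' @return ratio in `[0, 1]`, or `NA` if no qualifying CpG.
#' @export
mean_methylation <- function(records, region = NULL, coverage_min = 4L) {
  ob <- restrict_obs(obs_table(records), region,
                     qualifying_sites(records, coverage_min))
  if (nrow(ob) == 0L) return(NA_real_)
  mean(ob$call == 1L)
}

#' CHALM of a region
#'
#' Cell-heterogeneity-adjusted clonal methylation: `n_m / (n_m + n_u)`,
#' where a read counts as methylated if it has at least one methylated call
#' among its qualifying in-region CpGs and unmethylated if it has none.
#'
#' @inheritParams concurrence_ratio
#' @return ratio in `[0, 1]`, or `NA` if no qualifying read.
#' @export
chalm <- function(records, region = NULL, coverage_min = 4L) {
  ob <- restrict_obs(obs_table(records), region,
                     qualifying_sites(records, coverage_min))
  if (nrow(ob) == 0L) return(NA_real_)
  meth_read <- tapply(ob$call, ob$read, max)
  mean(meth_read == 1L)
}

#' Per-region metric bundle
#'
#' Computes concurrence (weighted and unweighted), mean methylation and
#' CHALM for each region.  In `"strict"` mode a region is dropped (all
#' metrics `NA`) if any of its covered CpGs falls below `coverage_min`; in
#' `"lenient"` mode only the failing CpGs are excluded.
#'
#' @inheritParams concurrence_ratio
#' @param regions interval table.
#' @param mode `"strict"` or `"lenient"` coverage handling (see above).
#' @return `data.frame` with one row per region: `name`, `chrom`, `start`,
#'   `end`, `n_cpgs`, `n_reads`, `concurrence`, `concurrence_unweighted`,
#'   `mean_meth`, `chalm`; the mode is recorded in attribute
#'   `"coverage_mode"`.
#' @export
region_metrics <- function(records, regions, coverage_min = 4L,
                           mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  ob <- obs_table(records)
  cc <- cpg_counts(records)
  out <- data.frame(
    name = if ("name" %in% names(regions)) regions$name else
      paste0("region", seq_len(nrow(regions))),
    chrom = regions$chrom, start = regions$start, end = regions$end,
    n_cpgs = NA_integer_, n_reads = NA_integer_, concurrence = NA_real_,
    concurrence_unweighted = NA_real_, mean_meth = NA_real_,
    chalm = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    inr <- cc$chrom == rg$chrom & cc$pos >= rg$start & cc$pos < rg$end
    if (!any(inr)) next
    if (mode == "strict" && any(cc$n_reads[inr] < coverage_min)) next
    sites <- cc[inr & cc$n_reads >= coverage_min, c("chrom", "pos")]
    if (nrow(sites) == 0L) next
    obi <- ob[ob$chrom == rg$chrom &
                paste(ob$pos) %in% paste(sites$pos), , drop = FALSE]
    obi <- obi[obi$pos >= rg$start & obi$pos < rg$end, , drop = FALSE]
    if (nrow(obi) == 0L) next
    lab1 <- obi$label[!duplicated(obi$frag)]
    out$n_cpgs[i] <- nrow(sites)
    out$n_reads[i] <- length(unique(obi$read))
    out$concurrence[i] <- sum(obi$label == "C") / nrow(obi)
    out$concurrence_unweighted[i] <- sum(lab1 == "C") / length(lab1)
    out$mean_meth[i] <- mean(obi$call == 1L)
    out$chalm[i] <- mean(tapply(obi$call, obi$read, max) == 1L)
  }
  attr(out, "coverage_mode") <- mode
  out
}
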