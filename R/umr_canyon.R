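# Undermethylated regions (UMRs) and methylation canyons.
#
# A CpG with per-CpG mean methylation below 10% (at coverage >= 4) is
# undermethylated; a maximal run of at least 4 consecutive undermethylated
# CpGs is a UMR; adjacent UMRs are merged when the merged span's mean
# methylation stays below 10%; UMRs spanning at least 3.5 kb are canyons.
# Canyons are split into aCanyons (active) and pCanyons (Polycomb) by
# whether their concurrence ratio exceeds a genome-background threshold:
# the 90th percentile of the best-fitting classical distribution
# (Cramer-von Mises selection among 7 families) of concurrence ratios of
# 10,000 non-overlapping random regions.

#' Call undermethylated regions from a per-CpG methylation track
#'
#' @param track `data.frame` with `chrom`, `pos` and `value` (per-CpG mean
#'   methylation), already restricted to CpGs passing the coverage filter;
#'   [meth_track()] produces this.
#' @param min_run minimum number of consecutive undermethylated CpGs
#'   (default 4).
#' @param max_meth methylation ratio below which a CpG is undermethylated,
#'   and below which the merged span's mean must stay (default 0.10,
#'   strict `<`).
#' @return interval table with `n_cpgs` and `mean_meth` per UMR; spans run
#'   from the first to one past the last member CpG.
#' @export
call_umrs <- function(track, min_run = 4L, max_meth = 0.10) {
  out <- list()
  for (chr in unique(track$chrom)) {
    tc <- track[track$chrom == chr, , drop = FALSE]
    tc <- tc[order(tc$pos), , drop = FALSE]
    low <- tc$value < max_meth
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_run)
    if (length(runs) == 0L) next
    umr <- data.frame(first = starts[runs], last = ends[runs])
    # Greedy left-to-right merging of consecutive UMR pairs, iterated to a
    # fixed point: merge when the mean methylation over every tracked CpG
    # in the merged span (including intervening CpGs) stays below max_meth.
    repeat {
      merged <- FALSE
      i <- 1L
      while (i < nrow(umr)) {
        span <- umr$first[i]:umr$last[i + 1L]
        if (mean(tc$value[span]) < max_meth) {
          umr$last[i] <- umr$last[i + 1L]
          umr <- umr[-(i + 1L), , drop = FALSE]
          merged <- TRUE
        } else {
          i <- i + 1L
        }
      }
      if (!merged) break
    }
    for (i in seq_len(nrow(umr))) {
      span <- umr$first[i]:umr$last[i]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = tc$pos[umr$first[i]],
        end = tc$pos[umr$last[i]] + 1L,
        n_cpgs = length(span), mean_meth = mean(tc$value[span]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      mean_meth = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select canyons among UMRs
#'
#' @param umrs output of [call_umrs()].
#' @param min_length_bp minimum span (default 3500).
#' @return the UMR rows whose span is at least `min_length_bp`.
#' @export
call_canyons <- function(umrs, min_length_bp = 3500L) {
  res <- umrs[umrs$end - umrs$start >= min_length_bp, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Place n non-overlapping intervals of given lengths uniformly on a genome
# described by chrom sizes; bounded rejection sampling.
place_nonoverlapping <- function(chrom_sizes, lengths, max_tries = 200L) {
  chroms <- names(chrom_sizes)
  placed_chrom <- character(0)
  placed_start <- integer(0)
  placed_end <- integer(0)
  w <- chrom_sizes / sum(chrom_sizes)
  for (len in lengths) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chr <- sample(chroms, 1L, prob = w)
      room <- chrom_sizes[[chr]] - len
      if (room <= 0) next
      s <- sample.int(room, 1L) - 1L
      e <- s + len
      on_chr <- placed_chrom == chr
      if (!any(on_chr & placed_start < e & placed_end > s)) {
        placed_chrom <- c(placed_chrom, chr)
        placed_start <- c(placed_start, s)
        placed_end <- c(placed_end, e)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place non-overlapping regions; genome too small")
    }
  }
  genomic_intervals(placed_chrom, placed_start, placed_end)
}

#' Sample non-overlapping background regions
#'
#' Draws `n` mutually non-overlapping random genomic regions, with lengths
#' resampled from a reference length distribution (typically the canyon
#' lengths, so the background measures concurrence at canyon-like scale)
#' or fixed.
#'
#' @param chrom_sizes named numeric vector of chromosome sizes (bp).
#' @param n number of regions (default 10000).
#' @param lengths integer vector to resample lengths from, or a single
#'   fixed length.
#' @param seed optional integer seed for reproducible placement.
#' @return interval table of `n` disjoint regions.
#' @export
sample_background <- function(chrom_sizes, n = 10000L, lengths,
                              seed = NULL) {
  with_seed(seed, {
    lens <- if (length(lengths) == 1L) rep(as.integer(lengths), n) else
      sample(as.integer(lengths), n, replace = TRUE)
    place_nonoverlapping(chrom_sizes, lens)
  })
}

BACKGROUND_FAMILIES <- c("norm", "lnorm", "beta", "gamma", "unif", "exp",
                         "logis")
FAMILY_NPAR <- c(norm = 2L, lnorm = 2L, beta = 2L, gamma = 2L, unif = 2L,
                 exp = 1L, logis = 2L)

#' Fit the background concurrence distribution
#'
#' Fits each of seven classical families (normal, log-normal, beta, gamma,
#' uniform, exponential, logistic) to background concurrence ratios by
#' maximum likelihood, scores each fit by the Cramer-von Mises distance,
#' and takes the 90th percentile of the best-fitting family as the canyon
#' classification threshold.  Families whose support excludes the data
#' (e.g. log-normal with zeros) are skipped with a note.
#'
#' @param values background concurrence ratios in `[0, 1)`; at least 100.
#' @param quantile threshold quantile of the best fit (default 0.90).
#' @return list of class `background_fit`: `fits` (per-family parameter
#'   lists), `cvm` (named distances), `skipped`, `best_family`,
#'   `threshold`.
#' @export
fit_background <- function(values, quantile = 0.90) {
  stopifnot(length(values) >= 100L)
  if (stats::sd(values) == 0) stop("degenerate background: constant values")
  fits <- list()
  cvm <- c()
  skipped <- c()
  for (fam in BACKGROUND_FAMILIES) {
    # capture.output: fitdistrplus prints start-value failures to stdout
    fit <- tryCatch({
      res <- NULL
      utils::capture.output(
        res <- suppressMessages(suppressWarnings(
          fitdistrplus::fitdist(values, fam, method = "mle"))))
      res
    }, error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$estimate)) {
      skipped <- c(skipped, fam)
      next
    }
    gof <- tryCatch(suppressWarnings(fitdistrplus::gofstat(fit)),
                    error = function(e) NULL)
    if (is.null(gof) || !is.finite(gof$cvm)) {
      skipped <- c(skipped, fam)
      next
    }
    fits[[fam]] <- as.list(fit$estimate)
    cvm[fam] <- unname(gof$cvm)
  }
  if (length(cvm) == 0L) stop("no distribution family could be fitted")
  # minimum CvM distance; ties broken by fewest parameters, then by the
  # listed family order
  ord <- order(cvm, FAMILY_NPAR[names(cvm)],
               match(names(cvm), BACKGROUND_FAMILIES))
  best <- names(cvm)[ord[1]]
  qfun <- get(paste0("q", best), mode = "function")
  threshold <- do.call(qfun, c(list(quantile), fits[[best]]))
  structure(list(fits = fits, cvm = cvm, skipped = skipped,
                 best_family = best, threshold = unname(threshold),
                 quantile = quantile, n = length(values)),
            class = "background_fit")
}

#' @export
print.background_fit <- function(x, ...) {
  cat(sprintf("background fit (n = %d): best family '%s', %.0fth-percentile threshold %.4g\n",
              x$n, x$best_family, 100 * x$quantile, x$threshold))
  cat("  CvM distances:", paste(sprintf("%s=%.4g", names(x$cvm), x$cvm),
                                collapse = ", "), "\n")
  if (length(x$skipped)) {
    cat("  skipped (support/convergence):",
        paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify canyons by concurrence against the background threshold
#'
#' Concurrence strictly above the threshold makes a pCanyon
#' (Polycomb-associated); otherwise an aCanyon (active).
#'
#' @param canyons canyon interval table with a `concurrence` column.
#' @param fit a [fit_background()] result (or a numeric threshold).
#' @return `canyons` with a `class` column in `{"aCanyon", "pCanyon"}`.
#' @export
classify_canyons <- function(canyons, fit) {
  thr <- if (is.numeric(fit)) fit else fit$threshold
  canyons$class <- ifelse(canyons$concurrence > thr, "pCanyon", "aCanyon")
  canyons
}

#' Assign target genes to canyons
#'
#' A gene is a target of a canyon iff its promoter or gene-body interval
#' overlaps the canyon by at least 1 bp.
#'
#' @param canyons canyon interval table.
#' @param genes gene-model `data.frame` (see [gene_promoters()]).
#' @return `canyons` with a `target_genes` list column.
#' @export
assign_targets <- function(canyons, genes) {
  prom <- gene_promoters(genes)
  body <- tryCatch(suppressWarnings(gene_bodies(genes)),
                   error = function(e) prom[0, ])
  hits_p <- overlap_pairs(canyons, prom)
  hits_b <- overlap_pairs(canyons, body)
  per_canyon <- lapply(seq_len(nrow(canyons)), function(i) {
    sort(unique(c(prom$name[hits_p$subject[hits_p$query == i]],
                  body$name[hits_b$subject[hits_b$query == i]])))
  })
  canyons$target_genes <- per_canyon
  canyons
}
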