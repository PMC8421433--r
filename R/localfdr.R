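# Replicate-free differential calling via the local false discovery rate.
#
# For per-gene differences d between two samples the absolute values are
# modelled as a two-group mixture: a half-normal null f0 (scale sigma0) and
# an unspecified alternative.  sigma0 is fitted by truncated maximum
# likelihood on |d| values inside the middle third of [0, null_band] --
# excluding the near-zero peak on the left and contamination by real
# signal on the right.  The marginal f is a Gaussian kernel density of
# |d|, reflected at 0 to respect the non-negative support.  The local fdr
# of gene j is f0(|d_j|) / f(|d_j|) (p0 <= 1 omitted, so this is an upper
# bound on the posterior null probability), and genes below the cutoff in
# the requested direction are flagged.

#' Per-gene metric differences between two samples
#'
#' @param metrics_a,metrics_b named numeric vectors of a promoter metric
#'   (e.g. concurrence, mean methylation or entropy) per gene, sample A
#'   minus sample B.
#' @return `data.frame` with `gene_id`, `d`, `abs_d`; genes missing in
#'   either sample are dropped and their count recorded in attribute
#'   `"n_dropped"`.
#' @export
metric_difference <- function(metrics_a, metrics_b) {
  common <- intersect(names(metrics_a), names(metrics_b))
  common <- common[!is.na(metrics_a[common]) & !is.na(metrics_b[common])]
  if (length(common) == 0L) stop("no genes shared between samples")
  d <- unname(metrics_a[common] - metrics_b[common])
  out <- data.frame(gene_id = common, d = d, abs_d = abs(d),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <-
    length(union(names(metrics_a), names(metrics_b))) - length(common)
  out
}

# Half-normal density / cdf with scale sigma (the underlying normal's sd).
dhalfnorm <- function(x, sigma) {
  ifelse(x < 0, 0, sqrt(2 / pi) / sigma * exp(-x^2 / (2 * sigma^2)))
}
phalfnorm <- function(x, sigma) {
  ifelse(x < 0, 0, 2 * stats::pnorm(x / sigma) - 1)
}
qhalfnorm <- function(p, sigma) stats::qnorm((1 + p) / 2) * sigma

#' Truncated maximum-likelihood fit of a half-normal scale
#'
#' Fits the scale of a half-normal distribution from observations known to
#' lie inside `[lower, upper]`, maximizing the interval-truncated
#' likelihood (an uncorrected MLE on a truncated sample would be
#' inconsistent).
#'
#' @param x observations inside the interval.
#' @param lower,upper truncation bounds, `0 <= lower < upper`.
#' @return the fitted scale `sigma`.
#' @export
fit_halfnorm_truncated <- function(x, lower, upper) {
  stopifnot(length(x) > 0, lower >= 0, upper > lower,
            all(x >= lower & x <= upper))
  if (stats::sd(x) == 0 && lower == 0) stop("degenerate (constant) sample")
  nll <- function(log_sigma) {
    s <- exp(log_sigma)
    z <- phalfnorm(upper, s) - phalfnorm(lower, s)
    if (z <= 0) return(.Machine$double.xmax)
    v <- -(sum(log(dhalfnorm(x, s))) - length(x) * log(z))
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  opt <- stats::optimize(nll, interval = log(c(upper * 1e-4, upper * 100)))
  exp(opt$minimum)
}

# Exact Gaussian KDE of non-negative data, reflected at 0; evaluated by a
# direct kernel sum so that brute-force recomputation agrees to numerical
# precision.
kde_reflect0 <- function(x, bw) {
  force(x); force(bw)
  function(t) {
    vapply(t, function(ti) {
      mean(stats::dnorm(ti, mean = x, sd = bw) +
             stats::dnorm(ti, mean = -x, sd = bw))
    }, numeric(1))
  }
}

#' Fit the local-fdr model and flag differential genes
#'
#' @param records output of [metric_difference()].
#' @param null_band absolute-difference bound below which genes are
#'   considered for null fitting (default 0.10, the conventional
#'   methylation-difference threshold).
#' @param cutoff local-fdr cutoff below which a gene is flagged
#'   (default 0.2).
#' @param direction `"up"` (d > 0), `"down"` (d < 0) or `"both"`; applied
#'   after the local-fdr threshold.
#' @param kde_bandwidth numeric bandwidth, or `NULL` for Silverman's rule
#'   on `abs_d`.
#' @param null_interval `"range"` (default): the fitting interval is the
#'   middle third of `[0, null_band]`; `"rank"`: the middle tercile of the
#'   below-band genes by rank.
#' @param min_null minimum number of genes below `null_band` required.
#' @param prefilter_abs optional pre-filter: drop genes with
#'   `abs_d < prefilter_abs` before fitting/flagging (used with entropy
#'   differences where a minimum notable change is imposed).
#' @return list of class `localfdr_model` with elements `sigma0`,
#'   `fit_interval`, `bw`, `density_f` (function), `cutoff`, `direction`,
#'   and `records` (the input annotated with `local_fdr` and `flagged`).
#' @export
fit_localfdr <- function(records, null_band = 0.10, cutoff = 0.2,
                         direction = c("both", "up", "down"),
                         kde_bandwidth = NULL,
                         null_interval = c("range", "rank"),
                         min_null = 50L, prefilter_abs = NULL) {
  direction <- match.arg(direction)
  null_interval <- match.arg(null_interval)
  if (!is.null(prefilter_abs)) {
    records <- records[records$abs_d >= prefilter_abs, , drop = FALSE]
  }
  a <- records$abs_d
  if (stats::sd(a) == 0) stop("all differences identical; null is degenerate")
  below <- a[a < null_band]
  if (length(below) < min_null) {
    stop(sprintf(paste0("only %d genes below the null band %.3g ",
                        "(need >= %d); widen null_band"),
                 length(below), null_band, min_null))
  }
  if (null_interval == "range") {
    lo <- null_band / 3; hi <- 2 * null_band / 3
  } else {
    qs <- stats::quantile(below, c(1 / 3, 2 / 3), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  mid <- below[below >= lo & below <= hi]
  if (length(mid) < 10L) {
    stop("too few genes in the null fitting interval; widen null_band")
  }
  sigma0 <- fit_halfnorm_truncated(mid, lo, hi)
  bw <- if (is.null(kde_bandwidth)) stats::bw.nrd0(a) else kde_bandwidth
  f <- kde_reflect0(a, bw)
  lfdr <- dhalfnorm(a, sigma0) / f(a)
  lfdr <- pmax(lfdr, .Machine$double.eps)
  dir_ok <- switch(direction,
                   both = rep(TRUE, nrow(records)),
                   up = records$d > 0,
                   down = records$d < 0)
  records$local_fdr <- lfdr
  records$flagged <- lfdr < cutoff & dir_ok
  structure(list(sigma0 = sigma0, fit_interval = c(lo, hi),
                 n_fit = length(mid), bw = bw, density_f = f,
                 cutoff = cutoff, direction = direction,
                 records = records),
            class = "localfdr_model")
}

#' @export
print.localfdr_model <- function(x, ...) {
  cat(sprintf(
    "local-fdr model: sigma0 = %.4g (half-normal, fit on [%.4g, %.4g], n = %d)\n",
    x$sigma0, x$fit_interval[1], x$fit_interval[2], x$n_fit))
  cat(sprintf("  KDE bandwidth %.4g; cutoff %.3g (%s); %d/%d genes flagged\n",
              x$bw, x$cutoff, x$direction, sum(x$records$flagged),
              nrow(x$records)))
  invisible(x)
}

#' Overlap classes of differential gene sets
#'
#' Partitions concurrence-elevated and mean-hypermethylated gene sets into
#' P1 (concurrence-elevated only), P2 (hypermethylated only) and P3
#' (both).
#'
#' @param flagged_concurrence,flagged_mean character vectors of gene ids.
#' @return list with `P1`, `P2`, `P3` and `sizes`.
#' @export
classify_overlap <- function(flagged_concurrence, flagged_mean) {
  p3 <- intersect(flagged_concurrence, flagged_mean)
  p1 <- setdiff(flagged_concurrence, flagged_mean)
  p2 <- setdiff(flagged_mean, flagged_concurrence)
  list(P1 = p1, P2 = p2, P3 = p3,
       sizes = c(P1 = length(p1), P2 = length(p2), P3 = length(p3)))
}

#' Filter an external per-region test table by p-value
#'
#' When replicates exist, differential regions come from an external
#' pre-defined-regions test; this helper applies the strict `p < cutoff`
#' filter to its output table.
#'
#' @param table `data.frame` containing a `p` (or `pvalue`/`p.value`)
#'   column.
#' @param cutoff retain rows with `p < cutoff` (default 0.005).
#' @return the filtered table.
#' @export
filter_replicate_test <- function(table, cutoff = 0.005) {
  pcol <- intersect(c("p", "pvalue", "p.value"), names(table))
  if (length(pcol) == 0L) stop("no p-value column found")
  table[table[[pcol[1]]] < cutoff, , drop = FALSE]
}
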