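# DNMT-TET co-occupancy at promoters.  ChIP-seq promoter intensities
# (log2 RPKM) are standardized across promoters; the joint regulation
# score of a promoter is the product of the min-max-rescaled standardized
# intensities of the two enzymes, so it is 1 only where both attain their
# maxima and 0 wherever either attains its minimum.

#' Standardize promoter binding intensities
#'
#' `pi = (x - mu) / sigma` across promoters, with `mu`, `sigma` the mean
#' and standard deviation of the log2 RPKM values.  Population (divide by
#' n) standard deviation by default, switchable to the sample estimator.
#'
#' @param rpkm_log2 named numeric vector: promoter -> log2 RPKM.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return named numeric vector of standardized intensities.
#' @export
standardize_intensity <- function(rpkm_log2,
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(rpkm_log2) < 2L) stop("need at least two promoters")
  mu <- mean(rpkm_log2)
  s <- if (sd_type == "population") {
    sqrt(mean((rpkm_log2 - mu)^2))
  } else {
    stats::sd(rpkm_log2)
  }
  if (s == 0) stop("zero variance across promoters")
  (rpkm_log2 - mu) / s
}

#' DNMT-TET joint regulation score
#'
#' For standardized intensities `pi_D`, `pi_T` over a common promoter
#' universe, the joint score is the product of the min-max-rescaled
#' intensities:
#' `Pi = (pi_D - min_D)/(max_D - min_D) * (pi_T - min_T)/(max_T - min_T)`,
#' which lies in `[0, 1]` by construction.
#'
#' @param pi_d,pi_t named numeric vectors of standardized intensities for
#'   the two enzymes; names must cover the same promoter universe.
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
joint_regulation_score <- function(pi_d, pi_t) {
  if (!setequal(names(pi_d), names(pi_t))) {
    stop("profiles must cover the same promoter universe")
  }
  pi_t <- pi_t[names(pi_d)]
  rng_d <- range(pi_d); rng_t <- range(pi_t)
  if (diff(rng_d) == 0 || diff(rng_t) == 0) {
    stop("degenerate intensity range (max equals min)")
  }
  (pi_d - rng_d[1]) / diff(rng_d) * (pi_t - rng_t[1]) / diff(rng_t)
}

#' Group promoters by enzyme co-occupancy
#'
#' Labels every promoter `D+T+`, `D+T-`, `D-T+` or `D-T-` by whether each
#' enzyme's standardized intensity exceeds a per-enzyme quantile cutoff
#' (default: median split).
#'
#' @inheritParams joint_regulation_score
#' @param quantile_cut quantile in `(0, 1)` defining the `+`/`-` split.
#' @return named character vector of group labels; the rule is recorded in
#'   attribute `"rule"`.
#' @export
group_promoters <- function(pi_d, pi_t, quantile_cut = 0.5) {
  stopifnot(quantile_cut > 0, quantile_cut < 1)
  pi_t <- pi_t[names(pi_d)]
  dpos <- pi_d > stats::quantile(pi_d, quantile_cut)
  tpos <- pi_t > stats::quantile(pi_t, quantile_cut)
  g <- paste0(ifelse(dpos, "D+", "D-"), ifelse(tpos, "T+", "T-"))
  names(g) <- names(pi_d)
  attr(g, "rule") <- sprintf("quantile:%g", quantile_cut)
  g
}

#' CpG ratio and promoter CpG-density class
#'
#' `ratio = (n_cpg * length_bp) / (n_c * n_g)`.  Promoters are classed as
#' high- (HCP), intermediate- (ICP) or low-CpG (LCP) by two thresholds.
#' The default thresholds (0.48, 0.75) follow the common promoter
#' CpG-class convention in the literature and are configurable.
#'
#' @param n_cpg,n_c,n_g counts of CpG dinucleotides, Cs and Gs.
#' @param length_bp sequence length in bp.
#' @param thresholds length-2 numeric `(low, high)` class boundaries.
#' @return list with `ratio` and `class` (`NA` when `n_c` or `n_g` is 0).
#' @export
cpg_ratio <- function(n_cpg, n_c, n_g, length_bp,
                      thresholds = c(0.48, 0.75)) {
  if (n_c == 0 || n_g == 0) {
    return(list(ratio = NA_real_, class = NA_character_))
  }
  r <- (n_cpg * length_bp) / (n_c * n_g)
  cls <- if (r >= thresholds[2]) "HCP" else if (r < thresholds[1]) "LCP"
         else "ICP"
  list(ratio = r, class = cls)
}

#' @rdname cpg_ratio
#' @param seq a character scalar DNA sequence; counts are derived from it.
#' @export
cpg_ratio_from_seq <- function(seq, thresholds = c(0.48, 0.75)) {
  s <- toupper(seq)
  count <- function(pat) {
    m <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  cpg_ratio(count("CG"), count("C"), count("G"), nchar(s), thresholds)
}
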