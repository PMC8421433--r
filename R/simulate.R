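# Synthetic epiread generator with closed-form ground truth.
#
# Reads are placed uniformly over a synthetic CpG map (by CpG index, not
# bp, to avoid spacing artifacts) and their calls follow a first-order
# Markov chain along the read: the first CpG is Bernoulli(p); each next
# CpG copies the previous state with probability rho and otherwise draws a
# fresh Bernoulli(p).  The stationary per-CpG methylation level is p for
# every rho, so rho is a pure within-read concordance knob.  For i.i.d.
# calls (rho = 0) the expected weighted concurrence of a k-CpG read set
# has the closed form (1 - p) * (1 - (1 - p)^(k - 1)); for rho > 0 the
# expectation is computed exactly by enumerating the 2^k patterns.

#' Simulation configuration
#'
#' @param n_cpgs number of CpGs on the synthetic map.
#' @param coverage target mean read coverage per CpG.
#' @param cpgs_per_read CpGs per read (k).
#' @param p_meth stationary per-CpG methylation probability, scalar or
#'   length-`n_cpgs` vector.
#' @param rho within-read Markov persistence in `[0, 1]`; 0 gives i.i.d.
#'   calls.
#' @param spacing_bp distance between consecutive CpGs: a scalar, a
#'   length-`n_cpgs - 1` vector, or a function `n -> integer vector`.
#' @param chrom chromosome name of the map.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cpgs = 2000L, coverage = 50, cpgs_per_read = 4L,
                       p_meth = 0.5, rho = 0, spacing_bp = 50L,
                       chrom = "chrS", seed = 1L) {
  stopifnot(all(p_meth >= 0 & p_meth <= 1), rho >= 0, rho <= 1,
            cpgs_per_read >= 1L, n_cpgs >= cpgs_per_read)
  structure(list(n_cpgs = as.integer(n_cpgs), coverage = coverage,
                 cpgs_per_read = as.integer(cpgs_per_read),
                 p_meth = p_meth, rho = rho, spacing_bp = spacing_bp,
                 chrom = chrom, seed = seed),
            class = "sim_config")
}

sim_cpg_map <- function(config) {
  n <- config$n_cpgs
  sp <- config$spacing_bp
  gaps <- if (is.function(sp)) sp(n - 1L) else rep_len(as.integer(sp),
                                                       n - 1L)
  as.integer(cumsum(c(100L, gaps)))
}

# Markov-chain calls for n reads of k CpGs with per-read per-position
# methylation probabilities p (n x k matrix) and persistence rho.
markov_calls <- function(n, k, p, rho) {
  calls <- matrix(0L, n, k)
  calls[, 1] <- stats::rbinom(n, 1L, p[, 1])
  if (k > 1L) {
    for (j in 2:k) {
      copy <- stats::rbinom(n, 1L, rho)
      fresh <- stats::rbinom(n, 1L, p[, j])
      calls[, j] <- ifelse(copy == 1L, calls[, j - 1L], fresh)
    }
  }
  calls
}

#' Simulate epireads under the Markov read model
#'
#' @param config a [sim_config()].
#' @return list with `records` (an [epireads] table), `cpg_map` (integer
#'   positions) and `truth` (see [ground_truth()]).
#' @export
simulate_epireads <- function(config) {
  map <- sim_cpg_map(config)
  k <- config$cpgs_per_read
  n_reads <- ceiling(config$n_cpgs * config$coverage / k)
  p <- rep_len(config$p_meth, config$n_cpgs)
  records <- with_seed(config$seed, {
    starts <- sample.int(config$n_cpgs - k + 1L, n_reads, replace = TRUE)
    pmat <- t(vapply(starts, function(s) p[s:(s + k - 1L)], numeric(k)))
    calls <- markov_calls(n_reads, k, pmat, config$rho)
    epireads(config$chrom, sprintf("r%d", seq_len(n_reads)),
             lapply(starts, function(s) map[s:(s + k - 1L)]),
             lapply(seq_len(n_reads), function(i) calls[i, ]))
  })
  list(records = records, cpg_map = map,
       truth = ground_truth(mean(p), k, config$rho))
}

# Exact pattern distribution of a k-CpG read under the Markov model.
pattern_distribution <- function(p, k, rho) {
  pats <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  prob <- apply(pats, 1, function(s) {
    pr <- if (s[1] == 1L) p else 1 - p
    if (k > 1L) {
      for (j in 2:k) {
        fresh <- if (s[j] == 1L) p else 1 - p
        pr <- pr * (if (s[j] == s[j - 1L]) rho + (1 - rho) * fresh
                    else (1 - rho) * fresh)
      }
    }
    pr
  })
  list(patterns = pats, prob = prob)
}

#' Expected metrics under the generative read model
#'
#' Expected weighted concurrence, mean methylation and 4-CpG entropy of an
#' infinitely deep library of k-CpG reads with stationary methylation
#' probability `p` and persistence `rho`.  For `rho = 0` the concurrence
#' expectation reduces to the closed form
#' `(1 - p) * (1 - (1 - p)^(k - 1))`; the general case enumerates the
#' `2^k` patterns exactly.
#'
#' @param p stationary methylation probability.
#' @param k CpGs per read.
#' @param rho Markov persistence.
#' @param log_base entropy base.
#' @return list with `concurrence`, `mean_meth`, `entropy` (entropy `NA`
#'   unless `k >= 4`; computed on the 4-CpG pattern distribution).
#' @export
ground_truth <- function(p, k, rho = 0, log_base = 2) {
  pd <- pattern_distribution(p, k, rho)
  c_per_pattern <- apply(pd$patterns, 1, function(s) {
    if (all(s == 1L) || all(s == 0L)) 0L else sum(s == 0L)
  })
  conc <- sum(pd$prob * c_per_pattern) / k
  ent <- if (k >= 4L) {
    pd4 <- pattern_distribution(p, 4L, rho)
    pr <- pd4$prob[pd4$prob > 0]
    -sum(pr * log(pr, base = log_base))
  } else {
    NA_real_
  }
  list(concurrence = conc, mean_meth = p, entropy = ent)
}

#' Closed-form expected weighted concurrence for i.i.d. calls
#'
#' @inheritParams ground_truth
#' @return `(1 - p) * (1 - (1 - p)^(k - 1))`.
#' @export
expected_concurrence_iid <- function(p, k) {
  (1 - p) * (1 - (1 - p)^(k - 1))
}

#' Plant undermethylated spans in a methylated background
#'
#' Simulates a library whose per-CpG methylation probability is the
#' background `config$p_meth` (choose it high, e.g. 0.8) except inside the
#' planted spans, where it drops to each span's `p_inside`.
#'
#' @param config a [sim_config()].
#' @param umr_spec `data.frame` with columns `start`, `end` (bp, 0-based
#'   half-open, non-overlapping) and `p_inside`.
#' @return list with `records`, `cpg_map`, and `truth_intervals`: per
#'   span, the first and last planted CpG position (the boundaries a
#'   correct UMR caller should recover).
#' @export
plant_umrs <- function(config, umr_spec) {
  o <- order(umr_spec$start)
  umr_spec <- umr_spec[o, , drop = FALSE]
  if (any(umr_spec$start[-1] < umr_spec$end[-nrow(umr_spec)])) {
    stop("planted spans overlap")
  }
  map <- sim_cpg_map(config)
  p <- rep_len(config$p_meth, config$n_cpgs)
  truth <- data.frame(chrom = config$chrom,
                      first_cpg = NA_integer_, last_cpg = NA_integer_,
                      n_cpgs = NA_integer_,
                      umr_spec, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(umr_spec))) {
    inside <- which(map >= umr_spec$start[i] & map < umr_spec$end[i])
    if (length(inside) > 0) {
      p[inside] <- umr_spec$p_inside[i]
      truth$first_cpg[i] <- map[inside[1]]
      truth$last_cpg[i] <- map[inside[length(inside)]]
      truth$n_cpgs[i] <- length(inside)
    }
  }
  config$p_meth <- p
  sim <- simulate_epireads(config)
  list(records = sim$records, cpg_map = map, truth_intervals = truth)
}

#' Paired simulations mimicking enzyme knockouts
#'
#' Produces a baseline library and a perturbed library sharing the CpG map
#' and seed.  `dnmt_down` pulls the methylation level toward 0 (loss of
#' methyltransferase), `tet_down` pushes it toward 1 (loss of
#' demethylase), `both_down` drives the within-read persistence toward 1
#' (reads become concordant), each of which lowers the expected
#' concurrence.
#'
#' @param config baseline [sim_config()].
#' @param mode one of `"dnmt_down"`, `"tet_down"`, `"both_down"`.
#' @param strength perturbation strength in `(0, 1]`; 1 is a full effect.
#' @return list with `baseline` and `perturbed` simulation results.
#' @export
simulate_knockout <- function(config,
                              mode = c("dnmt_down", "tet_down",
                                       "both_down"),
                              strength = 0.75) {
  mode <- match.arg(mode)
  stopifnot(strength > 0, strength <= 1)
  pert <- config
  if (mode == "dnmt_down") {
    pert$p_meth <- config$p_meth * (1 - strength)
  } else if (mode == "tet_down") {
    pert$p_meth <- config$p_meth + (1 - config$p_meth) * strength
  } else {
    pert$rho <- config$rho + (1 - config$rho) * strength
  }
  list(baseline = simulate_epireads(config),
       perturbed = simulate_epireads(pert))
}
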