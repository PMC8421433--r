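---
title: "Methylation concurrence from read-level bisulfite data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation concurrence from read-level bisulfite data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methconcur)
```

## The statistic and its assumptions

A bisulfite sequencing read reports the joint methylation state of
neighbouring CpGs on one DNA molecule from one cell. `methconcur` exploits
this to measure whether methylation (DNMT activity) and demethylation
(TET activity) act *concurrently* at a locus: an unmethylated CpG inside a
partially methylated read cannot be explained by a uniformly methylated or
uniformly unmethylated cell, so it marks molecules on which both processes
have left footprints.

Each read (restricted to its non-missing calls) is dissected into maximal
runs of equal state. A fully methylated read is one **M** fragment; a
fully unmethylated read is one **U** fragment; a mixed read alternates
**M** fragments with **C** (concurrence) fragments. The concurrence ratio
of a region is the C share of the total fragment weight,

$$\mathrm{concurrence} \;=\;
  \frac{\sum_c \omega_c}{\sum_c \omega_c + \sum_m \omega_m + \sum_u \omega_u},$$

with $\omega$ the fragment's in-region CpG count (weighted form) or 1
(unweighted form). The weighted form equals the fraction of C-labeled CpG
observations, which makes it well defined at a single CpG and gives the
per-CpG track its simple interpretation. It lies in $[0, 1)$: a read's
first fragment of a mixed read is always flanked by the opposite state, so
at least one observation per read escapes the C label (the supremum
$(k-1)/k$ is attained by a $k$-CpG read with exactly one methylated CpG).

Assumptions worth keeping in mind:

- a read is treated as one molecule; mate pairs must be merged upstream
  (the extractor counts overlapping mate bases once, first mate winning);
- CpGs are collapsed onto the forward-strand C coordinate, relying on the
  symmetry of CpG methylation;
- missing calls (`?`) do not break runs: dissection operates on the
  ordered non-missing calls, because the molecule is continuous even
  where the base call is not informative;
- fragment *labels* always come from the full read; only *weights* are
  clipped to the region. Clipping labels would misclassify a clipped
  mixed read as fully unmethylated, destroying the statistic's meaning at
  region borders. This is the single most consequential convention in the
  package.

For the unweighted ratio the package counts each clipped fragment once if
any of its CpGs lies in the region. Whether fragment counting should use
clipped or whole-read fragments is genuinely open; the clipped reading is
the default here because it keeps the unweighted ratio a function of the
same observation set as the weighted one.

## Companion metrics

Mean methylation is the methylated fraction of CpG calls; CHALM is the
fraction of reads carrying at least one methylated call. The
heterogeneity scores (Shannon entropy, Epipolymorphism $1 - \sum p_i^2$,
PDR) are computed on 4-CpG windows of adjacent CpGs, using only reads
that cover all four CpGs with non-missing calls; a region's score is the
unweighted mean over windows whose first CpG lies in the region
(first-CpG membership avoids double counting across abutting regions).
This per-read 4-CpG requirement is why heterogeneity scores use far fewer
reads than concurrence on short-read libraries — a contrast the test
suite asserts directly on simulated data.

**Entropy base.** The conventional presentation of methylation entropy
prints a natural-log formula yet quotes a 0–4 range for 4-CpG loci; the
range only holds for base 2 with 16 patterns. The package defaults to
base 2 so that the documented range is exact, and exposes
`log_base = exp(1)` for the natural-log variant.

Coverage filtering is uniform across metrics: CpGs covered by fewer than
`coverage_min = 4` reads are excluded before aggregation. Region bundles
(`region_metrics()`) offer a *strict* mode that drops any region
containing an undercovered CpG (the convention used when comparing
metrics across regulatory elements, where all metrics must see the same
CpGs) and a *lenient* mode that drops only the failing CpGs.

## Joint regulation score

Promoter binding intensities (log2 RPKM) of a methyltransferase and a
demethylase are standardized across promoters,
$\pi = (x - \mu)/\sigma$ (population $\sigma$ by default; the sample
variant is a switch, and the two differ only by a constant factor that
cancels in the min-max rescaling). The joint score is

$$\Pi = \frac{\pi^D - \pi^D_{\min}}{\pi^D_{\max} - \pi^D_{\min}} \cdot
        \frac{\pi^T - \pi^T_{\min}}{\pi^T_{\max} - \pi^T_{\min}} \in [0, 1],$$

zero wherever either enzyme attains its minimum and one only at joint
maxima. For the four co-occupancy groups (D+T+, D+T−, D−T+, D−T−) no
published threshold exists; the package defaults to a per-enzyme median
split — which reproduces a near-balanced partition — and exposes the
quantile as a parameter recorded in the output. CpG-density classes
(HCP/ICP/LCP) use the common literature thresholds 0.48 and 0.75 on the
CpG ratio $(\#\mathrm{CpG} \times L)/(\#C \times \#G)$; these are
conventions external to this package and are configurable.

## Local-fdr differential calling

With one tumor and one normal sample there are no replicates, so per-gene
differences $d_j$ of a promoter metric are assessed by a local false
discovery rate. Absolute differences are modelled as a two-group mixture
with a half-normal null $f_0$ and unspecified alternative; the reported
quantity $f_0(|d_j|)/f(|d_j|)$ omits the prior null probability
$p_0 \le 1$ and is therefore an upper bound on the posterior null
probability. Genes below the 0.2 cutoff, in the requested direction, are
flagged.

Numerical decisions:

- **Null fitting interval.** Genes with $|d| < 0.10$ (the conventional
  methylation-difference threshold) are candidates; of these only the
  middle third *of the range* $[0, 0.10]$, i.e. $|d| \in [1/30, 2/30]$,
  is used — the near-zero peak deviates from half-normal shape and the
  upper third risks contamination by true signal. A rank-tercile variant
  is available (`null_interval = "rank"`). The interval reading is the
  default because the exclusion argument is about *values* near zero, not
  ranks.
- **Truncated likelihood.** The half-normal scale is fitted by maximizing
  the interval-truncated likelihood. A naive MLE on the truncated sample
  would be inconsistent (it sees only tail values and overestimates the
  scale); the test suite checks recovery within 10% on truncated samples
  of 2,000 values across 20 seeds.
- **Marginal density.** Gaussian KDE with Silverman's bandwidth on
  $|d|$, reflected at zero to respect the non-negative support, and
  evaluated by an exact kernel sum rather than grid interpolation so that
  the density-ratio identity is reproducible to numerical precision.
- Direction gating happens after thresholding, so flag sets for
  "elevated" and "depleted" partition the sub-cutoff genes; negating all
  differences and flipping the direction yields the identical flag set.

Overlap classes of two flagged sets (concurrence-elevated vs
mean-hypermethylated) are plain set algebra: P1 = concurrence only,
P2 = mean only, P3 = both. When replicates exist the differential call
belongs to an external pre-defined-regions test; the package only filters
such a table at strict $p < 0.005$.

## UMR and canyon calling

Per-CpG mean methylation (coverage $\ge 4$) below 10% defines an
undermethylated CpG; a maximal run of $\ge 4$ of them is a UMR spanning
first to last member CpG; adjacent UMRs merge when the mean over all
tracked CpGs in the merged span (intervening ones included) stays below
10%. Merging considers consecutive pairs greedily left-to-right and
iterates to a fixed point, which is deterministic and insensitive to
restart order. UMRs spanning $\ge 3.5$ kb are canyons.

The aCanyon/pCanyon threshold comes from the genome background: the
concurrence ratios of 10,000 mutually non-overlapping random regions are
fitted by maximum likelihood to seven classical families (normal,
log-normal, beta, gamma, uniform, exponential, logistic) via
`fitdistrplus::fitdist`, each fit scored by the Cramér–von Mises distance
(`gofstat`), and the threshold is the 90th percentile of the best family.
Families whose support excludes the data (log-normal when zeros occur)
are skipped, not fatal; CvM ties break toward fewer parameters, then the
listed order. Classification is strict: concurrence *above* the
threshold makes a pCanyon. Background region lengths are resampled from
the canyon length distribution by default, so the background measures
concurrence at canyon-like scale; a fixed length is available. Canyon
target genes are genes whose promoter (TSS−1 kb to TSS+500 bp,
strand-oriented) or gene body (TSS+500 bp to TTS) overlaps the canyon by
at least 1 bp.

## Annotation statistics

- TSS-anchored binned methylation: 120 bins of 100 bp from 2 kb upstream
  to 10 kb downstream, strand-oriented, bin values coverage-weighted;
  per-bin Spearman correlation against expression over pairwise-complete
  genes with a 10-gene floor.
- Motif CPK: hits are assigned to regions by midpoint so a hit straddling
  a border counts once; fold enrichment is log2(CPK in aCanyons / CPK in
  pCanyons); if either CPK is zero, one pseudo-hit is added to both
  counts and the motif flagged.
- TF occupancy: the ratio of the occupied-canyon fractions of the two
  classes (a ratio of proportions, reported as the field's "odds
  ratio"); infinite when no pCanyon is occupied.
- Chromatin interactions: an anchor pair is *self-interacting* only when
  both anchors overlap the *same* region. Pairs spanning two different
  canyons are not covered by the exhaustive self/distant definitions
  unless "same region" is read strictly; the package labels them
  *distant-interacting*, which keeps the three labels a partition.
  Length-matched shuffled controls are seeded and preserve the length
  multiset exactly.

## The synthetic generator

Reads are placed uniformly over the CpG *index* space (placement by bp
would entangle coverage with CpG spacing). Calls follow a first-order
Markov chain: the first CpG is Bernoulli($p$); each subsequent CpG copies
its predecessor with probability $\rho$, otherwise draws a fresh
Bernoulli($p$). This keeps the stationary methylation level at $p$ for
every $\rho$, so $\rho$ is a pure within-read concordance knob. For
i.i.d. calls the expected weighted concurrence of $k$-CpG reads has the
closed form $(1-p)\,(1-(1-p)^{k-1})$; for $\rho > 0$ the package
enumerates the $2^k$ patterns exactly. Knockout emulations move $p$
toward 0 (methyltransferase loss), toward 1 (demethylase loss), or
$\rho$ toward 1 (both lost, reads concordant) — each lowers expected
concurrence from an interior starting point, mirroring the biological
expectation that losing either enzyme depletes concurrence.

The generator emulates read structure, stationary level, within-read
correlation and coverage. It does **not** model sequencing error,
bisulfite non-conversion, strand bias, spatially varying CpG density
correlated with methylation state, or fragment-length distributions.
Passing tests therefore certify the estimators and their conventions,
not robustness to those artifacts.

Default study conditions used across the test suite: $k = 4$ CpGs per
read, 50× coverage over 2,000 CpGs at $p = 0.5$, $\rho = 0$ for the
closed-form recovery; deep single-locus libraries (2,000 reads over one
4-CpG window) for entropy convergence; 5,000 genes with a 10% spike of
+0.3 shifts over a 0.02 null scale for the local-fdr operating
characteristics; 10,000 background draws for distribution selection;
planted UMR spans of ~4 kb at near-zero internal methylation in a highly
methylated background for boundary recovery. These sizes make every
property measurable in seconds while leaving estimation error well below
the asserted tolerances.

## Known limitations

- 5hmC is indistinguishable from 5mC in bisulfite data, so "methylation"
  here is their sum; concurrence involving oxidized intermediates cannot
  be resolved.
- The epiread extractor handles ungapped per-base alignments; indel-aware
  extraction from BAM/CRAM is out of scope (use an upstream extractor and
  the epiread TSV).
- The local-fdr assumes the null scale is estimable from the middle of
  the sub-0.10 band; heavily contaminated nulls (most genes truly
  differential) violate this.
- Distribution selection is only as meaningful as the candidate list;
  the seven families are the conventional choice, not an exhaustive one.
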