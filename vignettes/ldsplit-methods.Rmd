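---
title: "Allele-split association of SNPs with recombination hotspot intensity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-split association of SNPs with recombination hotspot intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ldsplit)
```

This vignette is the package's own account of the statistics it implements:
the allele-split association test, the recombination-rate estimator behind
it, the hotspot caller, the forward simulator used as the benchmark, and the
numerical choices made where the design was genuinely open.  It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The association model

Hotspot intensity cannot be observed per chromosome; what a phased panel
records is the *historical* recombination intensity of the sample's
ancestry, visible in linkage disequilibrium.  The test therefore uses a
population quantity as a proxy for the phenotype: the population
recombination rate $\rho = 4 N_e r$ per inter-SNP segment, integrated over
a hotspot's fixed physical boundaries into a *strength*
$\rho_\mathrm{hs} = \sum_j \rho_j \ell_j$ (units $\rho\cdot$kb, with
$\ell_j$ the overlapped segment length).

For a candidate SNP the chromosomes are partitioned by allele into two
subpopulations, the rate map is re-estimated for each side *with the same
estimator*, and the two strengths are contrasted as

$$\Delta\rho = \frac{\rho_0 - \rho_1}{\rho_0 + \rho_1} \in [-1, 1].$$

Only the contrast matters: every systematic property of the estimator
(scale, shrinkage, discretization) hits both sides identically, which is
what licenses substituting a different rate estimator than the one used in
the original LD literature (Section 3).

**Allele-age standardization.**  The rarer allele of a SNP is typically
younger; its carriers share a more recent common ancestor, have had less
time to accumulate crossovers, and consequently look spuriously "cold".
Left uncorrected, frequent alleles would be called "hot" across the board.
The correction is empirical: orient the contrast as frequent-minus-rare,
estimate $E(\Delta\rho)$ and $SD(\Delta\rho)$ among SNPs of *equal* minor
allele frequency on the same chromosome, and standardize,
$z = (\Delta\rho - E)/SD$.  "Equal MAF" is exact at the sample's
resolution: MAF is a multiple of $1/n_\mathrm{chrom}$, so bins are placed
on that grid and bins with fewer than two members are merged with their
nearest neighbor (`maf_bin_stats`).  The null-panel uniformity check in the
acceptance suite shows why this matters: with raw $\Delta\rho$ the
allele-split statistic is anti-conservative against a random-split null
(allele splits follow the genealogy; random splits do not), while the
standardized statistic is approximately uniform.

**Permutation null.**  Significance is assessed against `n_perm = 200`
random splits of the sample with each side at least 30% of chromosomes
(the MAF $\ge$ 0.3 floor for candidates guarantees observed splits obey the
same bound), with the hotspot boundaries held fixed and the rate maps
re-estimated per side.  The p-value is the proportion of null values whose
absolute (standardized) statistic strictly exceeds the observed one;
`p = 0` is reported as `0/n_perm`, with an optional $(k+1)/(n+1)$
correction flag.  Two permutation-size conventions are supported: the
default draws the smaller-side size uniformly over all feasible sizes
("ideal"), and a 50/50 mode with optional `keep_pairs` reproduces the
convention of reusing equal-size permutations with homologous chromosomes
kept together; the two give statistically indistinguishable p-values, and
`null_scan` additionally supports exact size-matching per test.

**Normality gate and outlier chromosomes.**  The p-value model assumes the
null $\Delta\rho$ scatter is normal around zero.  Hotspots failing a
Shapiro test (p < 0.05) are rejected from the scan; the gate is evaluated
on the same permutations that serve as the null (drawing a separate batch
would double the cost for no extra information); in practice such
failures are driven by a few chromosomes that are individually much hotter
or colder than the rest.  These are found by the *side score*
$S = \sum_{i} \pm|\Delta\rho_i|$ (gain when the chromosome sat on the
hotter side of permutation $i$), to which an iterative two-sided Grubbs
test is applied (statistic $G = \max|S - \bar S|/sd(S)$, p-value from the
$t$ distribution with $n-2$ degrees of freedom, removal threshold 0.1 so
borderline outliers near p = 0.05 are caught).  `retest_without_outliers`
reruns the single-pair pipeline on the reduced panel.

**Multiple testing.**  P-values across all hotspot–SNP pairs of a run are
mapped to Storey q-values with $\pi_0$ estimated at $\lambda = 0.5$;
q-values are monotone in p and capped at 1.

## 2. Scan geometry

Candidates for a hotspot are the SNPs inside it plus up to 200 SNPs beyond
each boundary, MAF $\ge$ 0.3.  Because rate estimation is local, each test
re-estimates rates in a sliding window of 500 segments centered at the
candidate SNP, discarding 50 segments at each (interior) end where the
estimate depends on data outside the window.  The window is extended when
necessary so that the hotspot interval itself always lies inside it — with
the default sizes this is automatic, but it protects smaller configurations
from integrating a strength over an uncovered interval.  Hotspot–SNP
distances are reported both in signed bp to the peak center (negative to
the left, 0 inside) and as the count of SNPs strictly between the candidate
and the proximal boundary SNP.

## 3. The rate estimator

The package deliberately does not depend on an external rjMCMC rate
estimator.  The estimator is a haplotype-copying (Li–Stephens/PAC)
penalized composite likelihood:

* Haplotype $k{+}1$ is modeled as an imperfect mosaic of the $k$ haplotypes
  before it in an ordering; copying switches templates across segment $j$
  with probability $1 - e^{-\rho_j d_j / k}$ and mismatches are absorbed by
  a Watterson-scaled mutation probability $\tilde\theta / 2(k+\tilde\theta)$.
* The composite log likelihood is averaged over `n_orderings = 6` random
  orderings drawn from the estimator's own seed.  Haplotype rows are first
  sorted lexicographically, so the estimate is exactly invariant to the row
  order of the input panel.
* Per-segment rates live on a shared log-spaced grid (25 values,
  $10^{-2}$–$10^{2}$ per kb); the grid floor is the estimator's lower
  boundary, reported for segments with no crossover signal.  A fused
  penalty of `block_penalty = 5` log-likelihood units per change of level
  between adjacent segments keeps maps blocky, in the spirit of the
  interval-penalty convention of LD-based rate estimation.

**Optimization.**  Conditional on scaled forward/backward vectors, the
likelihood profile of a *single* segment over the grid has the closed form
$\sum_h \log(e^{-g/k_h} A_{h,j} + (1-e^{-g/k_h}) B_{h,j})$, computed for
all segments in one forward–backward sweep (C++).  The penalized surrogate
— per-segment profiles plus the fused penalty — is maximized exactly by a
dynamic program over levels.  Because the profiles are exact only for
one-segment moves, jumping straight to the DP proposal can overshoot when
many segments move at once; each iteration therefore line-searches the
penalized *true* likelihood along a log-space path between the current and
proposed maps ($\alpha \in \{0.25, 0.5, 0.75, 1\}$) and the best visited
map overall is returned.  Four such cycles (`n_iterations = 4`) are ample
in practice; the iteration is deterministic given panel and config.

These defaults are free parameters of the artifact, validated by the
property suite (planted-hotspot recovery, flat-panel quiescence, null
uniformity) rather than by agreement with any external estimator: the
association statistic is a normalized within-run contrast, so only
*relative* rates matter.  Externally produced rate maps can be supplied via
the `rate_profile` TSV interface.

**Degenerate inputs.**  Estimation refuses fewer than 10 chromosomes
(LD-based estimation is underpowered on tiny subpopulations; this also
floors the permutation split sizes) and fewer than 3 SNPs.  Monomorphic
columns are retained but flagged, and excluded from candidate SNPs and
$r^2$.

## 4. Hotspot calling

On a piecewise-constant map, peaks are segments (or plateaus, which report
their midpoint) strictly above both neighbors.  A normal density
$a\,\varphi(x; \mu, \sigma) + b$ is least-squares fitted to the 50-kb
window around each peak (segment midpoints, length-weighted, Nelder–Mead
multi-started over initial widths 0.5/2/8 kb); fits are flagged degenerate
— and the peak dropped — when the window is flat, the fitted height is
below 5% of the window's range, or $\sigma$ leaves $(1, \mathrm{window})$.
FWHM $= 2\sqrt{2\ln 2}\,\sigma$.

Boundaries include the maximal contiguous run of segments containing the
peak whose rate exceeds a reference mean, within a span window of length
$\min(2\sigma, \mathrm{FWHM}, 50\,\mathrm{kb})$ centered at the fitted
peak.  Two open readings were resolved as follows:

* *"2 × fitted peak width"* is read as $2\sigma$ (the default), which
  analytically dominates the FWHM candidate; a `reading = "2fwhm"` switch
  provides the alternative.
* The *reference mean* is computed over the 50-kb fit window, not over the
  span window itself: on blocky maps a flat-topped peak can fill the whole
  span window, where it would never strictly exceed its own mean and every
  real call would be dropped.  A genuinely flat fit window still yields an
  empty run and drops the peak.

Overlapping adjacent calls have both boundaries moved to the midpoint of
the minimum-rate segment in the valley between their peak centers, applied
left to right.  Surviving calls are filtered to width $\le$ 20 kb and
average rate above 1 cM/Mb, converting $\rho$/kb to cM/Mb via
$r = \rho / (4 N_e)$ with a configurable $N_e$ defaulting to the
conventional human value 10,000.

## 5. The forward simulator

`evolve_population` implements a constant-size diploid Wright–Fisher
population on a 200-kb region with at most one crossover per meiosis
(matching one crossover per 200-Mb genome: background probability 0.001 in
the region).  A causal SNP controls a hotspot centered at 100 kb: the
crossover probability is multiplied by 10 in heterozygotes and 20 in hot
homozygotes, and hotspot breakpoints are drawn from a truncated normal at
the center.  Biased gene conversion is modeled mechanistically: with
probability 0.5 conditional on a crossover, the initiating haplotype — the
hot one, in heterozygotes — has a Gaussian-length tract (mean 500 bp)
centered at the breakpoint overwritten from its homolog before the flanks
are exchanged.  With the tract covering a heterozygous causal SNP this
yields a cold-allele fraction of $0.5 + 0.5\,p_\mathrm{BGC}$ among
recombinant gametes — 75% at the default, verified to binomial precision by
the acceptance suite.  This direction (hot initiates, hot→cold conversion)
is the only one consistent with that transmission distortion.

Neutral mutation is infinite-site: Poisson(`mutation_rate`) new sites per
haplotype per generation at fresh integer positions; sites fixed or lost
are removed.  The causal SNP enters as a single derived copy and its
hot-allele frequency is forced onto a linear trajectory between
`start_hot_freq` and `end_hot_freq` ("cooling" from 1, "heating" from 0)
by rejection-sampling whole offspring generations within a tolerance band
(`trajectory_tol = 0.02`; the budget errors out with diagnostics rather
than silently drifting).  Recurrent causal mutation, when enabled, flips
hot↔cold at 10× the background *per-site* rate
(`mutation_rate / region_length`).

Unspecified physical parameters are explicit config with documented
defaults: breakpoint $\sigma$ = 1,000 bp, tract $\sigma$ = tract mean / 5,
and `mutation_rate = 0.05` per haplotype per generation, calibrated once so
that the scaled benchmark runs below carry on the order of 100–300
segregating sites with MAF ≥ 0.05 at sampling time.

**What the simulator does and does not emulate.**  It reproduces the causal
mechanism the method targets (allele-controlled crossover intensity, BGC
transmission distortion, allele-frequency trajectories, recurrent mutation)
under a clean Wright–Fisher demography with uniform background
recombination and no gene conversion outside crossovers, no selection
beyond the trajectory forcing, no genotyping error, and no trio structure.
Passing benchmarks therefore demonstrates that the statistics recover a
known planted signal under the model's own assumptions — not that real
panels satisfy those assumptions.

## 6. Benchmark scales and what the tests compute

The test and acceptance runs use reduced problem sizes, chosen once as the
package's documented benchmark scales:

* *Direction benchmark*: 10 populations of 1,000 diploids evolved 500
  generations under the cooling model (end hot-allele frequency 0.5), 5
  samples of 90 individuals each; samples whose causal MAF falls below 0.3
  are discarded from evaluation.  Each sample is scored by whether the
  hot-allele subpopulation's estimated strength exceeds the cold's; ties
  count as incorrect (conservative, measure-zero for this estimator).
  Benchmark panels are thinned to MAF ≥ 0.05 (`filter_low_maf`) before
  estimation: rare variants carry almost no LD information relative to
  their likelihood cost.
* *Estimator recovery*: 30 replicates of 300 diploids / 250 generations;
  the planted-hotspot mean rate inside 95–105 kb must exceed the outside
  mean in ≥ 90% of replicates, and null replicates (no causal SNP) must
  yield no hotspot calls in ≥ 90%.
* *Null uniformity*: one neutral population (300 diploids, 1,200
  generations), a 30-individual panel, a fixed 6-kb test interval, and 50
  permutations per null; the standardized p-values across candidate SNPs
  are checked against uniformity by a Kolmogorov–Smirnov test at
  $\alpha = 0.01$.

The evaluation module scores scans against truth with tag-SNP de-duplication:
LD blocks at $r^2 \ge 0.8$ from a greedy maximal-bin clustering
(`select_ld_blocks`; ties broken by smallest index for determinism), block
tags are the causal SNP when present and otherwise the smallest-p member,
and positives are tags with p < 0.05.  Sensitivity, specificity and PPV
are reported with zero-denominator cases absent (`NA`), not zero.

## 7. Enrichment analyses

Candidate (q ≤ 0.01) and control (q > 0.5) SNPs are de-duplicated into LD
blocks per hotspot; for each candidate block up to two control blocks are
chosen whose block-center distances to the hotspot center best match the
candidate's (hotspots without available controls keep their candidates and
are reported).  Tags are extended to 200-bp windows — even widths place
the SNP one base right of center, by a documented floor/ceiling rule — and
overlaps with a feature track are counted with half-open semantics
(abutting intervals do not overlap).  Enrichment is the one-sided
hypergeometric tail probability of the candidate hit count with margins
fixed, computed by direct log-space tail summation and cross-checked in the
tests against both `fisher.test` and explicit enumeration.  All intervals
cross package boundaries as 0-based half-open BED; SNP positions are
1-based internally.

## 8. Known limitations

* The estimator is a composite likelihood on a rate grid; absolute rates
  are shrunken and discretized, and only within-run contrasts should be
  interpreted.
* Permutation p-values have resolution `1/n_perm`; q-values inherit it.
* The single-pair `split_test`/`retest_without_outliers` path compares raw
  $\Delta\rho$ (the chromosome-wide MAF standardization needs a full scan).
* Scans are single-locus and cis-local by construction; epistatic or
  trans effects are out of scope, as are phasing, imputation, multiallelic
  sites and sex chromosomes (panels must arrive complete and phased —
  loading rejects rather than imputes).
* Real-panel, chromosome-scale claims require external data and
  computation budgets beyond the test suite; the package accepts the
  published formats (HapMap phased text, phased VCF, rate-profile TSV) so
  such runs remain possible for users with the data.
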