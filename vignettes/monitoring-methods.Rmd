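---
title: "Monitoring variable communities with distance-based tests and multivariate control charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring variable communities with distance-based tests and multivariate control charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commchart)
```

## The model

All inference in `commchart` happens in Bray–Curtis dissimilarity
space.  Abundances $y_{ik}$ (sample $i$, taxon $k$) are fourth-root
transformed, a deliberately severe down-weighting chosen because
benthic communities routinely span three orders of magnitude of
numerical dominance: without it the one or two most abundant taxa
decide every result.  Pairs of samples are compared with

$$d_{ij} = \frac{\sum_k |y_{ik} - y_{jk}|}{\sum_k (y_{ik} + y_{jk})},$$

stored as dissimilarity on $[0, 1]$ (percent-similarity displays are a
reporting convention only).  Bray–Curtis is a *semimetric*: it is not
Euclidean-embeddable in general, which has concrete consequences
handled below.

The Gower-centred matrix $G = -\tfrac12 J D^{(2)} J$ (with
$D^{(2)}_{ij} = d_{ij}^2$ and $J = I - \mathbf{1}\mathbf{1}'/N$) turns
squared dissimilarities into an inner-product matrix whose trace is
the total sum of squares.  Every test statistic is a trace of
projected $G$; centroids never need explicit coordinates, only the
identity

$$\lVert c_A - c_B \rVert^2 = \frac{1}{n_A n_B}\sum_{i \in A, j \in B} d_{ij}^2
  - \frac{1}{n_A^2}\sum_{i<j \in A} d_{ij}^2
  - \frac{1}{n_B^2}\sum_{i<j \in B} d_{ij}^2 .$$

## Partitioning and permutation

`permanova_oneway()` partitions $\operatorname{tr}(G)$ by the hat
matrix of the group design; the pseudo-$F$ reduces exactly to the
classical ANOVA $F$ for Euclidean distances on univariate data (this
is a tested invariant, to $10^{-10}$, over random instances).
`permanova_twoway_mixed()` fits the crossed mixed model
(time fixed, plot random in the survey template) with Type III sums of
squares via sum-to-zero contrasts: each term's SS is
$\operatorname{tr}((H_f - H_{-t})\,G)$, the projection difference
between the full model and the model without that term.

*EMS convention.*  The mixed-model pseudo-$F$ denominators follow the
restricted expected-mean-squares rules by default: the fixed main
effect is tested over the interaction MS, the random main effect and
the interaction over the residual MS.  Both conventions circulate in
the distance-based ANOVA literature, so `ems = "unrestricted"` (both
main effects over the interaction MS) is retained as a switch; the
components-of-variation estimators change consistently with it.

*P-values.*  One-way designs permute raw rows of $G$ (unrestricted
permutation); the two-way design permutes residuals under the reduced
model — for each term, $G$ is residualised as
$(I - H_{red})\,G\,(I - H_{red})$, rows/columns are co-permuted, and
the full statistic recomputed.  The convention is
$P = (1 + \#\{F^\pi \ge F\})/(1 + B)$ throughout, with ties counted as
exceedances; whenever the number of distinct permutations is at most
$B$ the space is enumerated exhaustively and the exact $P$ reported
(this is compared against independent brute-force enumeration in the
tests for all designs with $N \le 8$).  One numerical subtlety: on
permuted residuals the denominator SS of the fixed term can be a
structural zero; numerator and denominator below
$10^{-12}\operatorname{tr}(G_{res})$ are classified as zeros
(giving $F = 0$ or $\infty$) rather than divided, so exhaustive
enumeration is reproducible across algebraically equivalent routes.

*Components of variation* are method-of-moments estimates from the
EMS (e.g. $\hat\sigma^2_{plot} = (MS_{plot} - MS_{res})/(n\,a)$ for the
balanced template).  Negative estimates are reported as zero with the
raw value retained; percentages are taken over the non-negative
estimates plus residual.  Unbalanced designs are refused rather than
approximated.

`permdisp()` tests homogeneity of multivariate dispersion: deviations
$z_i$ of each sample from its own group centroid, then a classical
one-way ANOVA $F$ on the $z_i$ with a label-permutation $P$.  It is the
companion test that decides whether a significant PERMANOVA term
reflects a shift in composition or merely a change in spread.

## Semimetric geometry

For semimetric input two things can go wrong, and the package makes
both visible rather than silently repairing them:

- **Centroid–centroid distances** from the $D^2$ identity can be
  slightly negative.  They are clipped to zero, each event is counted
  in `clip_diagnostics()` with the most negative value seen, and the
  unclipped value rides along as an attribute.
- **Per-sample deviations** (PERMDISP) use the signed convention: in
  the principal-coordinate embedding (`pcoa()`, which keeps
  negative-eigenvalue "imaginary" axes separately),
  $z_i^2 = (\text{real-axis part}) - (\text{imaginary-axis part})$,
  clipped at zero.  This matches the established distance-based
  treatment and avoids ordination corrections (Lingoes/Cailliez),
  which are deliberately out of scope.

Eigenvalues with $|\lambda| < 10^{-9}\max|\lambda|$ are treated as
numerical noise and dropped.

## Clustering and SIMPROF

`upgma()` is group-average fusion (merge height = arithmetic mean of
cross-pair dissimilarities, an invariant recomputed from scratch in the
tests).  Ties are resolved deterministically by ordering samples
lexicographically before clustering.  `simprof_test()` permutes each
taxon's values independently across samples — applied to the *same*
transformed matrix from which the dissimilarities were computed, so
profile and dissimilarities stay commensurable — and the random stream
is consumed in sorted-label order, making results invariant to row and
column order of the input.  Defaults are 1000 permutations for the mean
profile and 999 for the test; only the 5% level is anchored by the
monitoring convention.

`significant_clusters()` traverses the UPGMA tree top-down and stops
at nodes whose SIMPROF test is non-significant; subsets of fewer than
three samples are untestable and become terminal clusters.  One honest
consequence of full traversal: after a correct split into two truly
homogeneous groups, *both* children are retested at level $\alpha$, so
the probability of recovering exactly the right partition is capped
near $(1-\alpha)^2 \approx 0.90$ no matter how strong the structure.
The test suite therefore asserts exact recovery in at least 75% of
replicates and detection of the split in at least 95%, rather than a
bound no implementation of this traversal could meet.

## Control charts

A plot-time observation is the centroid of its replicate samples (the
survey plots one point per plot per year despite four replicates);
`chart_spec(replicate_level = TRUE)` charts raw replicates instead.
The **baseline** chart measures each year against the pooled replicate
set of the plot's first $m = 2$ years (press-sensitive); the
**sequential** chart measures year $t$ against all years up to
$t - 1$ (pulse-sensitive).  Deviations are reported on the Bray–Curtis
root scale, matching a 0–1 chart axis.  Baseline years are charted but
not flagged by default; the first sequential point ($t = 2$, a
single-year reference) carries an `unstable` annotation because the
running reference needs time to stabilise.

**Bootstrap limits.**  Within each plot independently, the time-point
observation sets are resampled with replacement (a cell travels with
its full replicate set) and assigned to positions $1 \dots T$ in draw
order; deviations are recomputed, pooled across all plots and sites,
and the 50th/95th percentiles recorded per draw — pooled over all
charted times for the baseline chart, per time index for the
sequential chart, whose deviation distribution genuinely changes as
the reference accumulates.  The plotted limit is the mean of the
bootstrap percentile distribution (10000 draws by default).
Percentiles use the type-7 linear-interpolation empirical quantile;
the rule is stated because alternative conventions exist and the
choice is visible at these small cross-sections.

*A known coarseness.*  The per-time sequential percentile is taken
across the plot cross-section.  With $k$ plots that is the type-7
95th percentile of $k$ values — for $k = 3$ essentially a near-max
order statistic, whose mean sits near the 75th–80th percentile of the
deviation distribution.  Observed self-exceedance of the sequential
95% limit is therefore well above 5% at small $k$; the time-pooled
baseline limit does calibrate (measured ~5–8% on a 3-plot × 20-year
stationary series, a tested invariant).  Consequently a single plot
crossing the sequential limit is weak evidence; the package's
event-level reading — used in its power tests — is *more than half of
all plots flagged at the same time*, which matches how a site-wide
climatic shock manifests.

Sites sampled without fixed plots are accommodated by
`assign_pseudo_plots()`: replicates at each time are randomly
partitioned into $k$ stable pseudo-plots (sizes differing by at most
one, deterministic under seed).

## The synthetic survey

`simulate_community()` emulates the repeated-survey design the
analysis assumes: by default 1 site × 3 plots × 5 years × 4 replicate
samples and 30 taxa.  Taxon base expectations form a geometric ladder
across `dominance_span = 3` orders of magnitude (the ladder is
deterministic so the span is exact).  Plot, year and plot×year effects
are per-taxon normal draws on the log scale
(`plot_sd = 0.5`, `time_sd = 0.3`, `interaction_sd = 0.2` by default —
spatial structure somewhat stronger than inter-annual turnover, with a
weaker interaction, which is the regime the monitoring problem
presupposes), and counts are negative binomial with shared dispersion
2 (variance $\mu + \mu^2/2$, strong overdispersion typical of benthic
cores).  `disturbance_pulse()` multiplies the expectations of a random
taxon fraction at one time; `disturbance_press()` compounds a log-linear
trend from an onset year.  Effects, disturbance-taxon selection and
count draws use separate named sub-streams of the master seed, so
injecting a disturbance into an existing simulation changes nothing
else — `inject_disturbance()` relies on this to produce matched
disturbed/undisturbed pairs, with ground truth recording exactly the
cells whose expectations changed.

The pulse fixture used in the detection-power tests sets the
multiplier to 20 on half the taxa: measured on the transformed
Bray–Curtis scale this makes the final-year community shift about
three times the stationary inter-annual shift — a large but plausible
analogue of a once-in-a-century climatic event (the fourth root damps
a 20-fold abundance change to roughly a doubling).

What the generator does *not* emulate: taxon–taxon correlation beyond
what shared effects induce, zero-inflation beyond the negative
binomial, environmental drivers (salinity/temperature series), or
taxonomic error.  Passing tests therefore demonstrate statistical
correctness of the machinery under a realistic abundance model, not
robustness to every property of real survey data.

## Problem sizes and determinism

The test suite runs calibration studies at 1000 simulations × 199
permutations (type-I error of PERMANOVA, PERMDISP and SIMPROF, all
required to fall in [0.03, 0.07] at $\alpha = 0.05$), detection power
at 200 simulations × 200 bootstrap draws on the full
3-site × 3-plot template, variance-component recovery at 500
simulations, and the exact-enumeration and Euclidean-limit oracles at
100 random instances each; the survey-scale workflow runs once at the
full 9999 permutations and 10000 bootstrap draws.  Every stochastic
stage takes an explicit seed, and the workflow fans a single master
seed out to named sub-streams (`simprof`, `permanova_<site>`,
`bootstrap_<type>`, ...) so toggling one stage never shifts another's
randomness; identical configuration and seed reproduce identical
output files hash-for-hash.

## Limitations

- Designs beyond one- and two-way crossed (nesting, covariates, three
  factors) are out of scope, as are NMDS and ordination corrections.
- Components of variation require balance.
- Sequential-chart limits are coarse at few plots (see above).
- Control charts signal, they do not attribute: an out-of-control
  point is a prompt for investigation, not a verdict of impact.
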