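---
title: "Methods: time-scale analysis of longitudinal gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-scale analysis of longitudinal gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutdrift)
```

## The problem

Repeated monthly stool sampling of the same healthy adults over several
years raises a set of linked questions: how much does an individual's gut
community composition fluctuate month to month, do samples drift further
apart the longer the interval between them, what fraction of the community
observed at one time point is still present months or years later, and
which external factors (beyond host identity) co-vary with composition?
`gutdrift` implements the complete analysis chain for these questions on
taxon-by-sample relative-abundance or count tables, together with a
synthetic cohort generator so every stage can be exercised and calibrated
without sequence data.

## Data model

All statistics operate on two tabular objects. An `abund_tbl` is a tibble
with a `taxon` column and one numeric column per sample, tagged with a
taxonomic level and a mode (`counts` or `relative`); relative columns must
sum to 1 within 1e-9 and counts must be non-negative integers. Sample
metadata is a tibble keyed by `sample_id` with `individual_id` and a
calendar **month index** (`year * 12 + month`), so the interval between two
samples is an integer number of calendar months. We use the calendar date
rather than ordinal time-point labels because monthly sampling schedules
have gaps: a schedule of 37 time points can span 44 calendar months, and
all interval-group definitions below are stated in months.

Bloom detection and Bray-Curtis work on relative abundances; the
source-attribution sampler needs counts. The conversion is always explicit
(`as_relative()`), never silent.

## Short-term blooms

A sample is a *short-term bloom* for a taxon when the taxon's relative
abundance is strictly greater than 5 times its average relative abundance
over **all** of that individual's samples (zeros included, candidate sample
included). The inclusive mean is the literal reading of the rule and makes
detection a deterministic single pass; `include_self = FALSE` gives the
leave-one-out variant, which can disagree near the threshold when an
individual has few samples. Taxa never observed in an individual cannot
bloom (no division by zero), and ties at exactly 5x are not blooms.

Two structural blind spots of the rule are worth knowing. First, a taxon
that is already dominant cannot exceed 5x its own mean after closure to the
simplex: with mean abundance $m$, the post-closure ceiling on fold change
is roughly $1/m$, so taxa above roughly 15-20% abundance are undetectable
at threshold 5 however hard they bloom. This is why bloom counts shrink at
coarser taxonomic levels, where each taxon is more abundant. Second,
repeated blooms of the same taxon inflate the mean they are each judged
against: a taxon blooming 50-fold in two of nine samples raises its own
mean enough that neither excursion reaches 5x. Both effects are properties
of the rule, not of this implementation, and both are covered by tests.

## Interval groups and the dissimilarity contrast

Bray-Curtis dissimilarity ($BC(u,v) = \sum_i |u_i - v_i| / \sum_i (u_i +
v_i)$, computed through vegan) is evaluated for every unordered sample
pair. Same-individual pairs are binned by calendar-month interval:

| group | interval (months) |
|-------|-------------------|
| M1    | 1 (two consecutive months) |
| Y1    | 2-12 |
| Y2    | 13-24 |
| Y3    | > 24 |
| D     | different individuals |

Same-individual pairs with interval 0 (duplicate months) are excluded
rather than forced into M1, because M1 is defined as *consecutive* months;
the metadata validator additionally rejects duplicate (individual, month)
pairs on ingest, so interval-0 pairs only arise with hand-built matrices.
Pairs are unordered here; the source-attribution stage below uses the same
pairs ordered earlier-to-later, because source tracking is directional
while Bray-Curtis is symmetric. Note that published group tallies of
within-individual comparisons are sometimes ordered counts (twice the
unordered count); `enumerate_pairs()` always reports each unordered pair
once, and the per-group `n` in every output makes the convention explicit.

## The permuted-time-point test

The scientific claim is directional: pairs with longer intervals should be
*more* dissimilar. The natural statistic is the Wilcoxon rank-sum $W$ of
the longer-interval group over the pooled dissimilarities of both groups
(midranks for ties). But pairwise dissimilarities that share a sample are
dependent, so the ordinary Wilcoxon reference distribution is invalid.
The test therefore builds its null by permutation of the *time points*:
the collection-month labels are shuffled uniformly at random among each
individual's samples while the dissimilarity matrix stays fixed, pairs are
re-binned by the permuted intervals, and $W$ recomputed. Because the
permuted months are the same multiset, the interval multiset is preserved
and only the pairing of dissimilarity to interval changes, which is
exactly the exchangeability being tested.

Implementation choices:

* 1000 permutations by default; critical values are the 90th/95th/99th
  percentiles of the null (the percentile set is configurable; no single
  convention exists).
* The p-value uses the add-one estimator
  $(1 + \#\{W_\text{null} \ge W_\text{obs}\})/(1 + R)$, which cannot be 0.
* One-sided ("longer interval more dissimilar") by default; two-sided
  doubles the smaller tail.
* Permutations leaving either group empty are discarded and redrawn up to
  $10R$ attempts — a safeguard for custom group bounds; with the standard
  all-pairs binning it cannot trigger (see above).
* Tests run per individual and pooled; pooling permutes within each
  individual independently and combines the groups across individuals.

Calibration is part of the acceptance suite: under an exchangeable null
(static community, multinomial noise only) the rejection rate at
$\alpha = 0.05$ over 200 simulated individuals must sit inside the
binomial 95% interval around 0.05, and under strong drift the test must
reject for at least 80% of individuals with 30 monthly samples.

## Source attribution (retained community proportion)

For every ordered same-individual pair, the earlier sample is the sole
known source, the later sample the sink, and a collapsed Gibbs sampler
estimates the fraction of sink reads attributable to the source versus an
*Unknown* source. Using exactly one known source per pair (rather than all
earlier samples jointly) keeps each estimate interpretable as "the
proportion shared across these two time points". The model is the
published Bayesian source-tracking model: each sink read $i$ of taxon $t$
carries a latent assignment $z_i$, resampled from

$$P(z_i = v \mid \cdot) \propto \phi_v(t) \, (n_v^{-i} + \beta),$$

where for a known source $\phi_v(t) = (y_{vt} + \alpha_1)/(Y_v + \alpha_1
T)$ is fixed at the source's smoothed frequencies, and for the Unknown
source $\phi_U(t) = (u_t^{-i} + \alpha_2 N)/(U^{-i} + \alpha_2 N T)$ is
learned from the reads currently assigned to it. Defaults follow the
published method: $\alpha_1 = 0.001$, $\alpha_2 = 0.1$, $\beta = 10$, 100
burn-in sweeps, 10 restarts with one recorded draw each; the reported
proportion is the posterior mean across restarts. The inner loop is
compiled (Rcpp) and draws from R's RNG, so `set.seed()` reproduces
estimates exactly; in `retained_fraction_by_interval()` each pair gets a
deterministic per-pair seed derived from the master seed, so results do
not depend on which other pairs are processed.

Sink and source are rarefied to a common depth (the minimum observed
depth, capped at 1000 reads by default) before sampling; an explicit depth
larger than any sample's total is rejected rather than silently padded.
The cap bounds per-pair runtime at a few tenths of a second while leaving
mixture-recovery error well under 0.05 (checked on 70/30 two-source
mixtures at depth 2000 in the acceptance suite).

One behaviour of the model matters for interpretation: the Unknown
source's smoothed distribution is nearly uniform over taxa, so sink reads
of taxa rarer than roughly $\phi_U$ are preferentially absorbed by
Unknown even when the sink equals the source exactly. For skewed,
few-dominant-taxa communities (real gut profiles, and this package's
simulator) self-attribution exceeds 0.9; for artificially flat
communities it can drop to 0.8-0.85. This is a depth-independent property
of the model, not an estimation artifact.

## Ordination

`pcoa()` implements classical scaling directly: double-center
$-\tfrac12 D^2$, eigendecompose, scale eigenvectors by the square root of
positive eigenvalues. Bray-Curtis matrices are generally non-Euclidean, so
negative eigenvalues occur; they are dropped without Cailliez/Lingoes
correction (none is applied in typical practice for this analysis) and
their total magnitude is reported so the approximation error is visible.
Proportions explained are relative to the positive-eigenvalue total. Axis
sign — arbitrary in any eigendecomposition — is fixed by making each
axis's largest-magnitude loading positive, so coordinates are
reproducible run to run. The implementation is cross-checked against
`stats::cmdscale` in the tests.

## Mantel factor screen

Each per-sample factor becomes a distance matrix (absolute difference for
numeric factors, 0/1 mismatch for categorical), and the Mantel statistic
is the Pearson correlation of the vectorised upper triangles (Spearman is
available; with no stated convention, Pearson on raw distances is the
default). Significance comes from jointly permuting rows and columns of
the factor matrix — entries of a distance matrix cannot be permuted
independently — with the same add-one, one-sided estimator as above. A
constant factor yields zero-variance distances; the result is flagged
undefined instead of dividing by zero. The screen reports Mantel $r$ as
the factor's influence score and leaves the nine factors uncorrected for
multiplicity (raw per-factor p-values, as is conventional for this kind
of descriptive screen). Sampled permutation p-values agree with exhaustive
enumeration within 0.02 on small instances (tested), and $r$ matches
`vegan::mantel` to machine precision (tested).

## Read-level QC

`qc_filter_reads()` trims the maximal run of sub-Q20 bases at the 3' end
of each read (a simple suffix scan — the classic rule says only that
low-quality bases "at the end" are removed, so no sliding window is used)
and drops reads shorter than 200 bp after trimming. The operation is
idempotent. Whole-dataset properties often quoted alongside (total
high-quality reads per sample, fraction of bases at or above Q30) are
reported in the QC tibble but never enforced as filters.

## The synthetic cohort generator

`simulate_cohort()` produces data with the statistical structure the
analysis assumes, with ground truth for recovery tests:

* **Schedule**: 7 individuals; a shared pool of 37 candidate months inside
  a 44-calendar-month window (October 2016 to May 2020); each individual
  contributes a uniformly drawn 15-31 of them. These defaults mirror a
  realistic multi-year monthly cohort of this design.
* **Individuality**: a community-level log-abundance profile (log-normal,
  SD 2, giving the skewed few-dominant-taxa shape of real gut profiles)
  plus individual offsets with `baseline_sd = 1`, which puts
  between-individual dissimilarity well above within-individual
  dissimilarity.
* **Drift**: a Gaussian random walk on latent log-abundance with per-month
  step `drift_sd = 0.1`, closed to the simplex by softmax; chosen over
  Dirichlet autoregressions for transparent control of the drift
  magnitude. Variance accumulates linearly in the gap, so expected
  dissimilarity grows with interval.
* **Turnover**: each month the composition mixes with a freshly drawn
  novel community at rate `retention_decay = 0.02` per month, so the
  expected fraction retained across a gap of $d$ months is
  $(1-0.02)^d$ — the ground truth the source-attribution stage must
  recover as a declining trend.
* **Blooms**: with probability `bloom_prob = 0.2` per sample, one
  uniformly chosen taxon is multiplied by `bloom_fold = 50` in the
  *observed* composition only (the latent state is untouched), so blooms
  are transient and abundance returns to its usual level at the next time
  point. The fold default sits far above the detection threshold so that
  closure still leaves most injected blooms detectable.
* **Counts**: multinomial at `seq_depth = 30000` per sample (the order of
  magnitude of a well-covered amplicon run); columns sum to the depth
  exactly.

`simulate_covariates()` fills the nine survey covariates (participant ID,
date, workspace, drug use, yogurt, fruit, travel, blood pressure, blood
sugar). One designated factor (workspace by default) is generated with a
tunable association to individual identity — each individual has a
preferred level with sampling weight $1 + \text{effect}$ against 1 — and
all others are independent of everything, giving a known null for
calibrating the Mantel screen.

What the generator deliberately does **not** emulate: phylogenetic
correlation between taxa, strain-level dynamics, compositional
overdispersion beyond multinomial, seasonal periodicity, and covariate
effects on composition other than through individual identity. Passing
tests on synthetic cohorts therefore demonstrate correctness and
calibration of the *procedures* under the stated model, not biological
conclusions about real cohorts.

## Problem sizes and determinism

The test suite runs the calibration studies at the scales stated above
(200 null individuals and 100 drifting individuals at 200 permutations for
the test's size and power; 10-seed recovery studies for the Gibbs sampler
and retention trend; 50 random cohorts for the bloom oracle), which keeps
the full suite under a few minutes on one CPU. The acceptance script runs
the complete pipeline once at the full default cohort size with 1000
permutations. Every stochastic step — simulation, rarefaction, Gibbs
chains, permutation tests — draws from R's RNG under an explicit seed
recorded in the output, and identical seeds give bit-identical results;
the run manifest's MD5 digests make that checkable end to end.

## Known limitations

* The bloom rule's dominant-taxon and repeated-bloom blind spots
  (discussed above).
* Bray-Curtis non-Euclideanity means dropped negative PCoA eigenvalues;
  proportions explained are relative to positive eigenvalues only.
* The Unknown component's uniform prior absorbs very rare taxa, biasing
  shared proportions slightly downward for long-tailed communities.
* The permutation test conditions on the observed schedule; individuals
  whose schedule cannot form both contrast groups are reported as skipped
  rather than tested.
* Mantel tests on factors that are themselves time-structured (date)
  inherit the temporal autocorrelation of the community; the screen is
  descriptive, not causal.
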