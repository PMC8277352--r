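---
title: "Methods: brain-wide c-Fos activity mapping with fosmap"
author: "fosmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-wide c-Fos activity mapping with fosmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosmap)
```

# The problem

Immediate-early-gene (c-Fos) mapping quantifies recent neural activity
as counts of immunolabeled nuclei per brain region. In the helping
behavior test (HBT), a free rat can release a conspecific trapped in a
restrainer; rats reliably help members of their own strain ("ingroup")
but not of an unfamiliar strain ("outgroup"). `fosmap` implements the
full downstream analysis for such a design: given subject-by-region
count tables across nine behavioral conditions (six social conditions
plus chocolate, trapped and non-tested baseline controls, 7--10 rats
each, 84 regions), it asks which activity patterns distinguish the
conditions, how regions co-activate, and which regions are specific to
the ingroup condition; given tracking, photometry and tracing tables it
computes the accompanying behavioral, calcium-signal and projection
statistics.

All inputs are plain CSV; the central container is `ActivityDataset`, a
`SummarizedExperiment` with regions in rows (metadata in `rowData`),
subjects in columns (`subject_id`, `condition` in `colData`) and `NA`
for missing counts.

# Data cleaning

`removeOutliers()` removes a count iff it is (a) more than 2 SD from
its own (condition, region) group mean **and** (b) strictly outside the
observed range of that region pooled over all *other* conditions. The
second clause is interpreted over the other conditions because an
extreme value trivially extends its own condition's range, which would
make the literal pooled reading vacuous. The rule is single-pass with
statistics computed on the data as given; this matches a procedure that
reports a fixed number of removals. Cells with fewer than two observed
values carry no SD and are reported as skipped rather than flagged.
Note a structural consequence of clause (a): a group of size $n$ bounds
its own z-scores by $(n-1)/\sqrt{n}$, so groups of 4 or fewer can never
yield a removal.

`imputeConditionMean()` replaces each missing value by its (condition,
region) mean; it is applied only where a method needs complete data
(PLS, eigen regions). Totals and correlations are missing-aware
instead.

# Task PLS

`runTaskPLS()` decomposes the mean-centered condition-by-region matrix
(rows: per-condition means; columns centered by the unweighted grand
mean of condition means, since group sizes are unequal and the contrast
is over conditions) by SVD. Each latent variable (LV) pairs a condition
contrast (left singular vector) with a region salience profile (right
singular vector).

* **Permutation test (default 500):** subject-to-condition labels are
  shuffled without replacement keeping group sizes, the matrix and SVD
  recomputed, and each LV's p-value is the add-one estimator
  $(\#\{d^{perm}_l \ge d_l\} + 1)/(n_{perm}+1)$ — never zero, uniform
  under the null (verified by simulation in the test suite).
* **Bootstrap (default 500):** subjects are resampled with replacement
  within their condition; resamples leaving a condition with fewer than
  two distinct subjects are redrawn and counted. Because SVD sign and
  order are arbitrary, each bootstrap solution is aligned to the
  observed one by an orthogonal Procrustes rotation **estimated on the
  condition saliences and applied to the singular-value-scaled region
  saliences** ($V S$). We first tried rotating $V$ alone toward the
  observed $V$; that deflates the bootstrap SE and produced an 18%
  false-positive rate at the 2.57 cutoff on null data, versus ~4.6% for
  the adopted scheme, which is also the standard task-PLS practice.
  The bootstrap ratio is observed scaled salience / bootstrap SE, and
  `reliableRegions()` applies the conventional 2.57 cutoff (the 99.5%
  normal quantile, 2.5758, truncated to two decimals).

# Co-activation networks

`correlationMatrix()` computes pairwise Pearson correlations between
region counts within one condition, using pairwise-complete
observations and marking any pair with fewer than 3 complete cases
invalid. `thresholdNetwork()` ranks off-diagonal pairs by |r| and keeps
the top fraction (default 10%) as unweighted edges; ranking is by
magnitude so that negative co-activations survive, with the sign kept
as an edge attribute. Ties with the cutoff value are all retained and
the realized fraction reported.

Threshold selection (`sweepThresholds()`) follows the scale-free /
connectivity logic: for each cutoff the **scale-free topology index**
is the $R^2$ of the regression of the log per-bin degree *density* on
the log bin-mean degree, signed so that decaying distributions score
positive. Binning is equal-occupancy (sparse degree histograms at 84
nodes) with up to 10 bins; with equal-occupancy bins the raw occupancy
is flat by construction, so the density (occupancy divided by bin
width) is the quantity regressed. Fewer than 3 occupied bins yields an
undefined (NA) index with a reason, never a silent 0. On symmetric
(dense random) degree distributions the fitted slope is near zero with
an unstable sign, so only the index *magnitude* is diagnostic there;
preferential-attachment graphs score > 0.5 and dense random graphs
stay near 0 (both verified in the tests). **Percent connectivity** is
the percentage of non-isolated nodes — deliberately distinct from
**density** $2E/(N(N-1))$, which is reported separately.
**Small-worldness** is $\sigma = (C/C_{rand})/(L/L_{rand})$ on the
largest connected component, normalized by the means over matched-size
Erdős–Rényi graphs (largest-component convention when a random
instance disconnects). The recommended cutoff is the smallest fraction
with a positive defined scale-free index and percent connectivity at or
above a configurable floor (default 50%).

`centrality()` reports degree and unnormalized shortest-path
betweenness (pairs split equally over multiple shortest paths, on the
binarized graph); `identifyHubs()` intersects the top 20% by each
metric, including boundary ties. `louvainCommunities()` is seeded
modularity maximization via igraph.

# The ensemble eigen-region procedure

A single network (one threshold, one clustering, one weighting) has
limited validity; the ensemble asks which regions are *robustly*
ingroup-specific across 40 analysis configurations
(`defaultConfigGrid()`): 5 threshold fractions (5--25%) × {Louvain,
tree cut} × {binary, soft power} × {baseline-only, broad reference}.
The published grid itself is not recoverable from the main text, so
this full factorial spans the stated dimensions and is fully
overridable via YAML (`readConfigGrid()`).

Per configuration:

1. **Clustering** on counts pooled over the compared conditions plus
   the reference group (the partition must be condition-agnostic since
   every subject needs a cluster score). Soft power is
   $a_{ij}=|r_{ij}|^\beta$ with $\beta$ auto-selected as the smallest
   integer in 1..20 reaching a scale-free index of 0.8 (fallback 6).
   The tree-cut path clusters $1-|r|$ (or $1-a$) by average linkage
   with an adaptive branch cut: the partition over $k = 2..\lfloor n/3
   \rfloor$ maximizing the mean silhouette width, followed by a hybrid
   step that reassigns members of clusters smaller than 3 to the
   nearest cluster when close enough (below the median dissimilarity)
   and otherwise marks them unclustered. This is our own adaptive
   procedure in the spirit of dynamic hybrid branch cutting; it
   recovers planted modules with ARI > 0.7 alongside Louvain in the
   test suite.
2. **Eigen regions:** regions are z-scored across subjects and each
   cluster is summarized by its first principal component score per
   subject, sign-anchored to correlate positively with the cluster's
   mean z-profile. Singletons pass through their standardized values.
3. **Multinomial logistic regression** per cluster: the eigen-region
   score (plus intercept) predicts membership in {ingroup, outgroup,
   reference}, reference as baseline, fitted by Newton iteration with a
   ridge penalty. Each contrast slope is tested with a **penalized
   likelihood-ratio test**, Bonferroni-corrected over clusters × 2
   contrasts at 0.05. Two numerical choices matter here, both made
   after measurement. First, Wald tests fail in exactly the regime this
   design invites: with 8--10 subjects per class a strong effect gives
   quasi-complete separation, the penalized Hessian flattens, and the
   Wald statistic *decreases* as the effect grows (Hauck–Donner; we
   measured essentially zero power at a +3 SD shift). The LRT is
   monotone in effect size and is what the classifier uses (Wald
   p-values are still reported, `test = "wald"` switches). Second, a
   near-zero ridge (1e-4) leaves the LRT of the *null* companion
   contrast inflated under the other contrast's separation (12.5%
   rejections at a corrected 2.5% level); the default λ = 0.1 restores
   calibration (5--7% at α = 0.05 in both regimes) at no measurable
   power cost.
4. **Tally:** each cluster is classified as significant for the
   ingroup only, outgroup only, both, or none; every region inherits
   its cluster's class (unclustered regions count as none), and counts
   are accumulated over configurations. A high ingroup-only ratio marks
   a region as uniquely important for the ingroup condition.

A design consequence worth stating: a lone region with a condition
effect inside a large condition-agnostic cluster is *invisible* to this
procedure — its cluster's eigen region dilutes it. The procedure finds
regions through their condition-specific co-activation cluster, which
is also how the recovery scenario below plants its signal.

# Behavior

Openers are rats that opened on **all** of the final three testing days
(strict reading; a latched final session, flagged in the records, is
skipped). Latencies of non-opening sessions are recorded at the 2400 s
cap — the experimenter half-opens the door at 40 min, bounding the
measurable latency — which guarantees heavy ties, so the Friedman
statistic includes the tie correction (mid-ranks; the tie-free case
reproduces `stats::friedman.test` exactly). Acquisition is tested with
Cochran's Q on the rats × days opening matrix.

Tracks are filtered by dropping samples moving faster than 30 cm/s
relative to the last retained sample (speeds recomputed across gaps, so
a single teleporting sample is removed without losing its neighbours);
reported velocities use central differences. Zone occupancy uses
half-open containment $[x_0,x_1)\times[y_0,y_1)$ so adjacent zones
partition the arena; an entry is an out→in transition and starting
inside is not an entry; time in zone attributes each inter-sample
interval to its starting sample, making time-in + time-out equal the
session duration exactly. `exportDayMinuteTables()` emits the tidy
rat × day × minute table for external mixed-model tooling (mixed models
themselves are out of scope).

# Photometry

`computeDff()` fits the 405 nm isosbestic control to the 470 nm signal
by OLS over the whole session (a single-session fit, not windowed),
subtracts the fitted motion component and divides by the session median
of the raw 470 nm trace. The residual property guarantees a ~0 *mean*
(not median) of the corrected trace, and the output is invariant to
affine rescaling of the control. The corrected trace's noise floor is
$\sigma\sqrt{1+b^2}/\mathrm{median}(s_{470})$ — control noise transmits
through the fit with the bleed coefficient $b$, which matters when
bounding what "artifact-free" should look like. Zone entries are 0→1
transitions of the in-zone mask; PSTHs average event-aligned segments
(±10 s default) with SEM dispersion, dropping partial-window edge
events; the pre/post test compares mean ΔF/F over [−1, 0) vs (0, +1] s
per event with a Wilcoxon signed-rank across events (per-event pooling
is the default unit; per-session pooling is a matter of passing
per-session event subsets). The in-zone vs out-of-zone comparison is a
paired t across sessions; for two levels the repeated-measures F equals
t², which the result carries in `extras`.

# Tracing

`colabelFraction()` computes the percentage of retrogradely labeled
(FG⁺) cells co-labeled for c-Fos, excluding (not zeroing) zero-FG
cells. `behaviorCorrelation()` correlates a region's co-label
percentage with door-opening percentage (Pearson, no multiplicity
correction by design), with the raw c-Fos correlation as the built-in
negative control. `openerGroupComparison()` fits a two-way
(group × region, with interaction) ANOVA per measure and reports
per-region contrasts Sidak-corrected over regions.

# The synthetic-data generators

Every pipeline stage is testable offline against generators that are
pure functions of a seeded spec.

* **Counts** (`simulateActivity()`): a log-normal–Poisson mixture. The
  log-mean of a cell is $\log(\text{baseline}) + \lambda_m z_{im} +
  \log(\text{effect}) + \epsilon$, with one shared standard-normal
  factor $z$ per module per subject (the simplest mechanism for block
  correlation), dispersion noise $\epsilon$, and the observed value the
  average of 2 Poisson replicate ROIs (hence continuous, like averaged
  ROI counts). Defaults are the study design: 9 conditions × 7--10
  subjects, 84 regions, 6 modules, loading 0.6, dispersion 0.25,
  baseline 30 counts, 2% missing.
* **Behavior** (`simulateBehavior()`): designated openers (default
  75%) draw an acquisition day (days 2--8) and open every day after it
  with latency decaying exponentially toward a 120 s floor; non-openers
  never open. Tracks are reflected random walks with an optional
  attraction toward the restrainer zone.
* **Photometry** (`simulatePhotometry()`): both channels share drift
  and a smoothed motion artifact (scaled by a bleed coefficient into
  the 470 nm channel); transients are double-exponential kernels
  (rise 0.2 s, decay 1.5 s) at the planted event times. Ground truth is
  stored in the session for recovery tests.
* **Tracing** (`simulateTracing()`): the target region's co-label
  percentage is slope × door-opening percentage plus noise; other
  regions are uncorrelated.

What the generators do **not** emulate: anatomical spatial structure,
inter-regional distance effects, session-to-session drift in counts,
GCaMP kinetics beyond the two-time-constant kernel, or agent-like
movement. Passing recovery tests therefore demonstrates that the
*estimators* recover what the model plants at realistic sizes — not
that real tissue satisfies the model.

## Scenario parameters used by the tests and acceptance script

Problem sizes were chosen to exercise the study scale while keeping the
default test run in minutes: PLS recovery plants a 1.4× elevation of
both HBT conditions over all 84 regions at module loading 0.3 (199
permutations, 30 seeds); salience recovery plants 1.7× on one
14-region module (200 bootstraps, 15 seeds); the ensemble recovery
plants a 1.8× *ingroup-only* effect on one full module with that
module's loading at 0.2 and dispersion 0.1, so that the condition
effect itself binds the cluster — the paper-style situation in which
the procedure is designed to find a region (10 seeds × 40
configurations). Null calibrations use 300--1000 simulations per test.

# Known limitations

* The ensemble's published 40-configuration grid is a reconstruction
  (full factorial over the stated dimensions); results for any other
  grid are one YAML file away.
* The adaptive tree cut is a silhouette-guided stand-in for the
  dynamic hybrid algorithm's spirit, not a reimplementation of its
  exact control flow.
* The scale-free index's sign is uninformative for symmetric degree
  distributions; use its magnitude (and the sweep) there.
* With fewer than ~5 subjects per (condition, region) cell the outlier
  rule cannot fire (own-group z-scores are bounded), and bootstrap
  ratios at n = 7--10 per condition are approximate; the 2.57 cutoff's
  measured null FPR is ~4%, not the nominal 1%.
* `opener_power()` reports the exact one-sided Fisher enumeration; at
  n = 8 with 70% vs 0% opener incidence it gives ~94%, consistent with
  a 95% design claim whose exact test variant is unstated.
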