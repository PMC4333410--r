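---
title: "Methods: population statistics and the transcriptome success path"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population statistics and the transcriptome success path}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewirepath)
```

# The experimental system

A rewired strain carries one essential histidine-biosynthesis gene under a
foreign, doxycycline-inducible promoter at a non-native chromosomal locus,
with GFP co-expressed from the same promoter and RFP expressed
constitutively. Under histidine starvation, survival depends on whether
stochastic fluctuations of the rewired gene — visible as the per-cell **GFP
bias**, GFP FI / RFP FI — happen to reach an expression state that supports
growth. Strains fall into three fates: good survivors recover near-native
growth, poor survivors grow slowly, failures show no detectable growth. The
package quantifies both the single-cell picture (flow cytometry) and the
genome-wide picture (expression time courses), and tests whether the
genome-wide changes of surviving strains align along one direction in gene
space — the success path.

# Models and procedures

## Flow-cytometry statistics

Gating labels events rather than deleting them. An event at or beyond a
channel's range limit on *any* channel is `out_of_range`; the boundary is
inclusive because saturation piles events up exactly at the limits. Bead and
debris gates are axis-aligned boxes supplied by the analyst (instrument gate
coordinates are never portable between set-ups; the defaults in
`default_gates()` are sized to the synthetic generator's clusters).
Overlapping bead/debris boxes are rejected rather than resolved by
precedence, because silent precedence hides configuration errors.

Population statistics are computed per replicate first (mean and SD of bias
and of forward scatter over cell events), then averaged across replicates,
with standard errors taken across replicates — so the error bars reflect
biological reproducibility, not event-count shot noise. SDs are arithmetic
on the raw scale by default; whether the original analyses used raw or
log-scale SDs is not recoverable, so `population_stats(log = TRUE)` provides
the alternative.

The significance test behind "the starved population's statistic increased"
is deliberately a *convention*: a one-sided Welch two-sample t-test on the
per-replicate summary statistics (typically n = 4 per condition). With
identical inputs it returns P = 0.5, and a shift in the wrong direction
gives P > 0.5.

Growth rate is `mu = ln(Ct/C0)/t` (h^-1) from initial/final concentrations
and culture time; concentrations come from the bead ratio
`n_cell / n_bead x bead_conc`.

## Expression processing

All operations are affine on the log scale and therefore agnostic to the
logarithm base of the input. Normalization shifts each sample column
additively to a common mean (the simplest transform achieving a common
logarithmic mean; multiplicative on the raw scale) and is idempotent.
Filtering removes genes whose normalized value falls below -1.5 in **any**
sample. The quantifier is a design choice: the downstream change matrix,
PCA and clustering all need a complete genes x conditions block, so a gene
unreliable in one sample is unreliable for the row-wise analyses;
`rule = "all"` and `rule = "mean"` are available for sensitivity analysis.
Replicates are averaged arithmetically on the log scale.

The change matrix subtracts each strain's rich-medium (+His) profile from
its starvation states. Two presets mirror the study design of eight strains
(six growing, two failures without a late sample, three replicates, 90
arrays total):

* clustering preset: states {-His 2 h, -His >10 h} plus an explicit zero
  baseline row per strain -> 8 + 8 + 6 = 22 rows. The 10-min state is
  excluded here because a growth rate estimated over ten minutes is
  dominated by counting noise.
* PCA preset: states {-His 10 min, -His 2 h, -His >10 h}, no baseline ->
  also 22 rows.

Baseline rows carry no growth rate in the change matrix: the growth-change
correlations downstream (cluster centroids against growth, normalized
distance against growth) compare starvation states with starvation growth,
and the rich-medium regime — maximal growth at identically zero change —
belongs to a different physiological regime that would only distort those
correlations.

## Rank-product differential expression

For each comparison column (a starved replicate minus a rich replicate;
all replicate pairings by default, since the replicates are biological and
unpaired), genes are ranked by fold change with rank 1 the most changed in
the stated direction and average ranks on ties (which preserves invariance
under monotone transforms). The rank product is the geometric mean of a
gene's ranks. Significance uses the standard expected-false-positives
construction: within-comparison permutations give null rank products, and

```
pfp(g) = E[# null RP <= RP(g)] / rank(g)
```

estimates the proportion of false positives among genes called at RP(g).
Internally the comparison uses rank *products* rather than geometric means:
products of (average) ranks are exact in floating point, so ties between
null and observed values count correctly. An exact mode enumerates all
`n^K` rank tuples for tiny instances — per-gene ranks are marginally uniform
under within-column permutation, and linearity of expectation makes the
across-gene dependence irrelevant for the expected count — which the test
suite checks against an independently coded enumeration oracle.

## The success path

PCA is the SVD of the column-centered change matrix; genes are *not* scaled
to unit variance because change values already share the log-expression
scale and scaling would inflate low-variance genes (`scale = TRUE`
overrides). The PC1/PC2 "correlation line" is fitted by **total least
squares** (the major axis of the 2-D score cloud): both coordinates are PC
scores with no dependent/independent asymmetry, so orthogonal residuals are
the only defensible loss; OLS is available behind a flag for sensitivity.
Failure strains are excluded from the fit — the biological claim is that
survivors align and failures drop off — but their projections and orthogonal
residuals are still reported, so "dropping off" is a measurable quantity,
not an assumption.

The normalized distance of a condition is its orthogonal projection's
arc-length coordinate along the fitted line, measured from the projection of
the zero-change (+His) state, affinely rescaled so the included conditions
span [0, 1]. The line direction is oriented away from that origin, which
makes distances and loading tails invariant under PC sign flips (PCA signs
are arbitrary). Growth-distance correlation excludes 10-min bins by default
for the growth-noise reason above.

The path loading maps the unit line direction back to gene space through
the loading columns (unit norm by orthonormality). Tails take the
`floor(0.05 x n)` most positive and most negative genes — 169 per tail at
the study's 3398 retained genes; `floor` rather than rounding fixes the
truncation convention to match that printed count. Ties break by stable
gene order.

## Enrichment

The enrichment test is the **binomial** upper tail P(X >= k),
X ~ Bin(n, m/N) — selection treated as sampling at the set's background
frequency — matching the stated test of the original analysis; the
hypergeometric tail (sampling without replacement) is available behind a
flag. The universe is the retained-gene set (the 3398-analog), not the whole
genome. Size filters are per annotation kind: regulons and functional
categories need *more than* 15 members (strictly: a 15-gene regulon is
excluded), GO-like terms need 15 to 1000 inclusive — "fewer than 15 ...
excluded" reads naturally as >= 15 inclusive, and that convention is
flagged in the documentation. Bonferroni multiplies by the number of sets
tested per annotation kind per tail (the family is configurable to "all"),
with significance at adjusted P < 0.001.

## Clustering

Genes are observations, their 22 condition change values the coordinates,
Euclidean distance on the shared log scale. The cluster count is not
derivable from the study description, so it is an explicit argument
(default k = 10). Initialization uses `stats::kmeans` (Hartigan-Wong) with
`n_init = 50` random starts under a fixed seed, keeping the best inertia;
this serves the same stability purpose as k-means++-style seeding with the
field's standard implementation. Per-cluster growth correlation uses
conditions with defined growth; constant centroids are reported as missing
with a reason rather than erroring the batch.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, realistic choices, not tuning knobs.

* **Design**: eight strains (native control; good survivors hisB, hisC,
  hisF; poor survivors hisA, hisI; failures hisD, hisG), four time points
  (+His, -His 10 min, -His 2 h, -His >10 h; failures lack the late point),
  three replicates -> 90 samples.
* **FCM events** are log-normal mixtures (flow channels are positive and
  heavy-tailed; parameters are geometric mean and CV, with reporter CVs of
  25-50% and rich-medium growth ~0.7 h^-1, typical for *E. coli* in minimal
  medium). GFP is drawn as bias x RFP, so the planted bias distribution is
  exactly the GFP/RFP ratio. Beads are a tight bright high-scatter cluster,
  debris dim and low-scatter, and a configurable fraction of cells saturate
  at the instrument limits.
* **Expression**: log expression = baseline + s_i * g + DE offsets + noise,
  with `g` a unit direction supported on 10% of genes (adaptive
  reorganization touches a subset of the transcriptome) and per-condition
  progress s_i. The late-state progress is proportional to the planned
  starvation growth rate, so growth is affine in progress by construction;
  the 2-h state sits at 60% of the late progress; the 10-min state at 5%,
  reflecting the observed lag of roughly ten minutes before significant
  changes. Failure strains stay at zero on-path progress and are displaced
  orthogonally to `g` at 2 h ("dropping off" is true by construction).
* **Noise**: the per-sample, per-gene residual SD defaults to 0.03 log
  units. The microarray noise model of the original data is not published,
  so this is a package choice: it corresponds to a ~7% replicate CV
  (technically clean arrays after model-based signal extraction), and it
  places the two leading principal components of the change matrix at
  roughly half of the total variance — the regime reported for this kind of
  starvation time course, where the trajectory is detectable but far from
  noise-free. Growth rates receive N(0, 0.02 h^-1) noise around the affine
  map.

What the generator does **not** emulate: probe-level microarray artifacts,
intensity-dependent (heteroscedastic) noise, correlated gene modules beyond
the planted direction, batch effects, and any mechanistic link between the
rewired gene's dose and growth. Passing recovery tests therefore shows the
pipeline is correct and well-calibrated under its own model assumptions —
not that the biological conclusions of any particular data set are right.

# Numerical choices and degenerate inputs

* Range-limit gating is inclusive at both ends.
* TLS refuses isotropic score clouds (eigenvalue gap below `tol` times the
  leading eigenvalue) instead of returning an arbitrary axis.
* Normalized distance refuses coinciding projections; two conditions give
  distances {0, 1} by construction.
* pfp counting uses exact rank products with a 1e-12 relative guard on
  equality; up/down call sets are made disjoint by keeping the smaller-pfp
  direction in the (practically impossible) event of a double call.
* `filter_low` errors when every gene would be removed; `gfp_bias` errors
  on non-positive RFP naming the offending events; zero-variance inputs to
  any correlation are errors, except constant cluster centroids, which are
  reported as missing so one degenerate cluster cannot abort a batch.

# Problem sizes used in validation

The test suite validates parameter recovery at the full study scale
(3398 genes x 90 samples) over 100 generator seeds, oracle equivalence of
the rank product on 1000 random tiny instances (<= 6 genes, <= 3
comparisons) against exhaustive enumeration, binomial tails against pmf
summation for n, m, N <= 30, and null calibration of both error-controlling
procedures over 10,000 light-weight repetitions (40 genes x 3 comparisons
with 100 permutations; 24 annotation sets over a 200-gene universe). These
sizes keep the planted-signal regime of the study while making the
simulations cheap to repeat.

# Known limitations

* The rank-product permutation null assumes exchangeable genes within a
  comparison; strongly correlated gene blocks would make pfp optimistic.
* The binomial enrichment tail ignores the without-replacement correction;
  for selections that are a large fraction of the universe the
  hypergeometric flag is the better choice.
* TLS line fitting assumes comparable score scales on the two components;
  that holds here because both are PC scores of the same decomposition.
* Gate boxes are axis-aligned only; no density-based or elliptical gating.
* The generator's one-dimensional trajectory is a model of the *claim*, not
  of all possible transcriptome geometries; pipelines validated here can
  still be misled by data violating the single-direction assumption, which
  is exactly what the failure-residual diagnostics are for.
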