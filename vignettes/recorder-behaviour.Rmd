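---
title: "Quantifying recorder behaviour: metrics, axes and their design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying recorder behaviour: metrics, axes and their design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`recorderAxes` turns a flat table of occurrence records into a
per-participant description of recording behaviour. This vignette sets
out the model behind each metric, the numerical choices made where the
underlying definitions leave room, what the built-in simulator does and
does not emulate, and the package's known limitations.

## The data model

The atomic unit is a *record*: participant, taxon, observation date
(the date the organism was seen, not when it was submitted) and a point
location in a planar, metric coordinate system. Rows failing validation
(unparseable date, non-finite coordinates, empty identifiers) are
dropped and counted, never silently fixed. Duplicate rows are kept:
list-length metrics are defined over submitted records, and inventing a
deduplication rule would change them.

Two derived units matter throughout:

* an **active day** — a calendar day on which the participant observed
  at least one record;
* a **visit** — the unique combination of participant, date and 1 km
  grid square. Cells are assigned by flooring coordinates
  (`floor(x/1000), floor(y/1000)`), which is deterministic and
  translation-consistent; data supplied in longitude/latitude are
  refused rather than approximated, since 1 km squares are only
  meaningful in a projected CRS.

Participants active on 10 or fewer days are removed before analysis
(`min_active_days = 11`). Several metrics — periodicity needs gaps,
kernel areas need spread — cannot be estimated stably below roughly
that much data, and such transient participants would otherwise
dominate the fitted axes. The threshold is a single configuration
value, and `sensitivity()` reruns everything under alternatives
(7/10/15 by default) and reports rank correlations of the axis scores
over shared participants.

## Temporal metrics and the summer window

Recording of seasonal taxa concentrates in a few months; a participant
who joins in August should not score as "inactive" for the spring they
were never recording in. All four temporal metrics are therefore
computed inside per-year **summer windows**: the day-of-year range
containing the central 95% of *all* records in that year. Two choices
here are genuinely open and resolved as follows:

* **Quantile convention.** Window bounds are inverse-CDF
  (order-statistic, type-1) quantiles at `(1±coverage)/2`, rounded
  outward (floor below, ceiling above). With this convention the window
  provably contains at least the requested fraction of the year's
  records; interpolated quantile types can leave slightly more than
  `1 - coverage` outside even after rounding, which we verified on
  random draws before fixing the choice.
* **Windows are a dataset property.** They are computed on the full,
  unfiltered dataset, before transient participants are removed —
  everyone's records say when the recording season was.

The metrics themselves:

* **Activity ratio** divides in-window active days by the number of
  in-window calendar days between the participant's first and last
  in-window active day. The span is inclusive, so one active day gives
  ratio 1 rather than 0/0. Days between summers count for nothing —
  neither numerator nor denominator.
* **Weekly activity** is the median number of active days per ISO-8601
  week, over weeks with at least one active day, so absences between
  recording bouts do not dilute it. ISO weeks are a convention: the
  metric is unchanged by date shifts of whole weeks, but not by
  arbitrary one-year calendar shifts, which realign weekdays.
* **Periodicity** is the median gap between consecutive active days
  *within* a year's window; gaps never span the winter between two
  summers. Gaps are pooled across years before the median (rather than
  medianed per year and averaged): most participants have few gaps per
  year, and pooling is the more robust estimator. A participant with no
  within-year pair of active days has undefined periodicity — a missing
  value, never zero.
* **Periodicity variation** is the sample SD (n−1) of the same pooled
  gaps, undefined with fewer than two gaps.

## Spatial metrics

The spatial metrics describe the kernel-density surface of a
participant's record locations (all records, not only in-window ones):
the area of the 95% percent-volume region ("active area", km²), the
number of its disjoint parts ("recording areas"), and the 60%/95% area
ratio ("spatial aggregation").

Numerical construction, in order:

* **Kernel and bandwidth.** Bivariate-normal product kernel with the
  ad-hoc reference bandwidth `h_ref = sqrt((var_x+var_y)/2) · n^(−1/6)`
  (metres), the long-standing default of home-range kernel software.
  It is overridable; no data-driven (cross-validated) bandwidth is
  offered.
* **Grid.** 256 × 256 cells over the points' bounding box padded by 3
  bandwidths per side. The padding keeps the off-grid mass below about
  1% (asserted in tests); the surface is then renormalised to integrate
  to exactly 1 on the grid. Halving the cell size changes areas by
  under 2% at this resolution.
* **Percent-volume region.** Grid cells are sorted by density and
  accumulated greedily from the densest down until the target mass is
  reached — the standard discrete percent-volume-contour construction.
  Areas are cell counts × cell area. By construction the 60% region is
  nested in the 95% region, so spatial aggregation is always in (0, 1].
* **Part counting.** Disjoint parts are connected components of the
  selected cells under 8-connectivity (diagonal contact joins); holes
  inside a part do not split it.
* **Degenerate inputs.** Fewer than 5 distinct locations, or zero
  variance on both axes, make the KDE meaningless: such participants
  get missing spatial metrics and are excluded (complete-case) from the
  spatial PCA. They are never assigned zero area.

For an isotropic Gaussian cloud the construction can be checked in
closed form: the area containing mass *L* is `2πσ²·ln(1/(1−L))`, so
aggregation tends to `ln(2.5)/ln(20) ≈ 0.306` independent of σ — the
kernel's variance inflation cancels in the ratio. The acceptance tests
verify this at n = 5,000, together with exact nesting and ×4 area
scaling under coordinate doubling.

One caveat worth knowing: the reference bandwidth is computed from the
*overall* spread of a participant's points, so a participant with
several recording areas far apart is smoothed with a wide kernel. Very
widely separated areas remain distinct (the parameter-recovery study
plants three areas at 50× their spread and recovers all three), but
areas separated by only a few bandwidths will merge. This is a known
property of reference-bandwidth kernels on multimodal data, not a bug.

## Data-content metrics

* **Rarity values** rank taxa by record count over the whole dataset
  (commonest rank 1) and map ranks linearly onto [1, 100]:
  `1 + 99·(rank−1)/(S−1)` for S taxa. Taxa tied on count share the mean
  of their ranks' values — mean-rank sharing avoids order-of-appearance
  artefacts. The ranking uses the *full* dataset (including transient
  participants' records): the pool of what was recorded is a property
  of the project, not of the filtered cohort. **Rarity recording** is
  the participant's median per-*record* rarity value minus the dataset
  median — medians over records, not distinct taxa, so repeatedly
  recording a common species keeps pulling the metric down. The whole
  dataset treated as one participant scores exactly 0.
* **Proportion of taxa** is distinct-taxa-of-participant over
  distinct-taxa-of-dataset. For projects spanning regions larger than
  participants plausibly travel, both content metrics can be restricted
  to a region — a named polygon, or a circular buffer around a
  participant's records — which recomputes the taxon pool and rarity
  ranking inside it. The default is the whole dataset.
* **Single-species lists** is the fraction of a participant's visits
  with exactly one record.

## From metrics to axes

Five right-skewed metrics (active area size, number of recording areas,
periodicity, periodicity variation, activity ratio) are
`log10(x + 0.001)`-transformed; the offset keeps defined zeros finite
(a zero maps to −3). Every metric is then centred and scaled (sample
SD). A zero-variance column is a hard error naming the column —
proceeding would silently produce NaNs downstream.

Each group (temporal, spatial, content) is analysed separately — the
groups were constructed without an a-priori dependence between them,
and separate analyses keep the axes interpretable. Within a group the
analysis is complete-case: a participant missing any metric of the
group (undefined periodicity, degenerate KDE) is dropped from that
group's PCA only, and the exclusion is logged. Centres and scales are
computed on exactly the rows entering each group's PCA, so one
(centre, SD) pair per metric fully specifies the transform for later
projection.

PCA is by singular value decomposition (`prcomp`); because the columns
are standardised, covariance and correlation PCA coincide. PCA
components are defined only up to sign, so each named axis is oriented
by an **anchor metric** forced to load positively:

| axis | component | anchor |
|---|---|---|
| recording intensity | temporal PC1 | activity ratio |
| spatial extent | spatial PC1 | active area size |
| recording potential | content PC1 | proportion of taxa |
| rarity recording | content PC2 | rarity recording metric |

This replaces any post-hoc "take the inverse of component so-and-so"
description with a deterministic rule: refitting on reordered rows, or
with an SVD that happens to flip a sign, yields identical axes.
`write_loadings()` serialises loadings, centres, scales and log offsets
to CSV, and `project_axes()` applies them to new participants without
refitting — the mechanism for cross-study comparison. Projecting the
training data reproduces the training scores to numerical precision
(asserted to 1e−10).

`axis_correlations()` reports Pearson r and two-sided p-values for all
axis pairs and against log₁₀ records per participant; the recording
potential × rarity recording pair is flagged as orthogonal by
construction whenever both come from a single content PCA fit. A
combined 10-metric PCA is available behind `config$combined_pca` as
output only, with no orientation guarantees — the per-group analysis is
the primary one.

## Clustering and its support

Before accepting continuous axes, the package tests for discrete
behavioural groups: k-means for k = 2…5 (25 k-means++ initialisations
per k, best within-cluster sum of squares kept, all under one seed).
The number of clusters is chosen by the **Simple Structure Index**; its
three-component product form is documented in
`simple_structure_index()`: for standardised columns *j* and cluster
centres with ranges `r_j`,

* *a* — proportion of columns whose centre range exceeds the column SD;
* *b* — mean of `r_j / max(r)` over those columns;
* *c* — cluster-size evenness, taken as `min(size)/max(size)`.

`ssi = a·b·c`. The evenness form was chosen after comparing candidates
on planted-cluster constructions: entropy-based evenness barely
penalises shaving a genuine cluster into fragments and over-selected k,
while the min/max ratio recovers the planted number of clusters
reliably (20/20 seeds in the acceptance construction, three unit-SD
blobs 10 apart) and rejects a single blob as unsupported 20/20.

Support is judged by **average silhouette width** at the selected k
(Euclidean distance, silhouette 0 for singleton clusters, via the
`cluster` package): ASW below 0.5 means the clusters are not well
supported and the continuous axes are the better description. The
boundary is inclusive — exactly 0.5 counts as supported, since the rule
is "*less than* 0.5 fails".

## The simulator: what it emulates, and what it does not

`simulate_dataset()` generates records from explicit behavioural
parameters, one recorder at a time:

* **Temporal**: each day of a season (default days 91–273,
  April–September, over 4 years starting 2014) is active independently
  with probability `p_active`. This matches the Bernoulli assumption
  under which activity ratio estimates `p_active`; it does not emulate
  weather dependence, weekends, holidays or behavioural drift.
* **Spatial**: each visit draws a recording area from a weighted
  mixture and a location from an isotropic normal around its centre.
  Real recording is network-constrained (roads, reserves, gardens) and
  far from Gaussian.
* **Content**: taxa are drawn per visit without replacement with
  probability ∝ `rate^(1−rarity_bias)` from a geometric rank-abundance
  pool (default 50 taxa, decay 0.9, about a 175-fold commonest-to-rarest
  rate range). `rarity_bias = 0` mirrors the pool, 1 is uniform, above
  1 favours rarities. List length is `1 + Poisson`, truncated to the
  pool. There is no phenology, no spatial turnover in the species pool,
  and no detectability model.

Passing tests on simulated data therefore demonstrate that the metrics
measure what they claim *under the generative assumptions* — parameter
recovery, monotonicity, sign behaviour — not that any particular real
dataset will show the same axis structure. `random_profiles()` defines
the default heterogeneous cohort (activity probabilities from
Beta(1.2, 6) plus a 0.02 floor, 1–3 recording areas over a 100 km
domain with 300–3000 m spreads, 1–4 year histories, rarity biases
N(0, 0.4), mean list lengths 1–4); these values were fixed once as a
plausible opportunistic-scheme cohort and are not tuned per test.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use: 500-recorder cohorts for
the pipeline and threshold-sensitivity analyses; 5,000 points for the
Gaussian isopleth geometry; 20 replicates per profile for parameter
recovery; 20 seeds for cluster-selection recovery; and 50 randomized
tiny record sets compared against independent brute-force
implementations of every temporal and content metric (exact for
integer/median arithmetic, 1e−10 for floats). Every stochastic step
takes an explicit seed; `run_all()` is deterministic given its config,
and rerunning writes byte-identical outputs.

## Known limitations

* No geographic-CRS support: records must arrive projected; the package
  refuses lon/lat rather than guessing a projection.
* Reference-bandwidth KDE oversmooths strongly multimodal recording
  patterns (see above); cross-validated bandwidths are out of scope.
* Rarity is internal to the dataset — no external red-list or
  conservation-status weighting.
* Vague dates (ranges, "summer 2015") are dropped at load, not
  interpolated.
* Axes are fitted per dataset; comparing studies requires projecting
  through a shared loadings file, and axes of very different projects
  may not be comparable in meaning even then.
* Refitting published per-participant metrics requires the original
  study's metrics file, which is not redistributed with this package;
  `axes_from_metrics()` accepts any such CSV with mapped column names.
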