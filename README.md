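# recorderAxes

Participants in opportunistic biological recording projects — wildlife
recording apps, atlas schemes, portal-based citizen science — choose for
themselves when, where and what they record. That freedom produces large
datasets, but also strong individual-level biases in space, time and
species composition that propagate into occupancy models, species
distribution models and trend estimates. `recorderAxes` quantifies this
behavioural variation from the occurrence records alone: no survey
metadata (duration, effort, completeness) is required.

## What it computes

From a table of records (participant, taxon, date, location) the package
derives **ten per-participant metrics** in three groups:

**Temporal** (computed inside per-year *summer windows*, the day-of-year
range holding the central 95% of each year's records, so that metrics do
not simply reflect when someone joined):

* *activity ratio* — in-window active days / in-window days between the
  participant's first and last active day (inclusive);
* *weekly activity* — median active days per ISO week, over weeks with
  any activity;
* *periodicity* — median gap (days) between consecutive active days
  within a summer (never across years);
* *periodicity variation* — sample SD of those gaps.

**Spatial** (kernel density estimate of the participant's record
locations, bivariate-normal kernel with the reference bandwidth
`h_ref = sqrt((var(x)+var(y))/2) * n^(-1/6)`):

* *active area size* — area (km²) of the 95% percent-volume polygon;
* *number of recording areas* — count of its disjoint parts;
* *spatial aggregation* — area(60%) / area(95%), in (0, 1].

**Data content**:

* *proportion of taxa recorded* — participant's distinct taxa / dataset
  distinct taxa;
* *rarity recording* — median per-record *rarity value* (taxa ranked by
  dataset record count, mapped linearly so commonest = 1, rarest = 100)
  minus the dataset median;
* *single-species lists* — fraction of the participant's *visits*
  (unique date × 1 km grid square) with exactly one record.

Participants active on 10 or fewer days ("dabblers") are removed before
analysis (threshold configurable; 7/10/15 sensitivity built in).

Five right-skewed metrics are `log10(x + 0.001)`-transformed, all are
centred and scaled, and each group is analysed two ways:

* **k-means scan** (k = 2…5, k-means++ restarts) scored by the Simple
  Structure Index for choosing k and by average silhouette width (ASW)
  for support — ASW < 0.5 means clusters are not well supported;
* **PCA**, yielding four continuous, deterministically sign-oriented
  **axes of participant behaviour**: *recording intensity* (temporal
  PC1), *spatial extent* (spatial PC1), *recording potential* (content
  PC1, proportion-of-taxa positive) and *rarity recording* (content
  PC2, rarity-metric positive), plus correlations among axes and with
  log₁₀ records per participant.

A generative simulator (`species_pool()`, `recorder_profile()`,
`simulate_dataset()`) produces record tables with controllable seasonal
activity, spatial mixtures, rarity preference and list lengths, and
`recovery_study()` checks that the metrics recover the planted
parameters.

## Worked example

```r
library(recorderAxes)

pool     <- species_pool()                      # 50-taxon rank-abundance pool
profiles <- random_profiles(150, seed = 42)     # heterogeneous simulated recorders
records  <- simulate_dataset(profiles, pool, seed = 43)

res <- run_all(records, config = list(seed = 44))
print(res$axes)
```

```
records: 39834 rows, 150 participants
filter: 146/150 participants retained (2.7% removed), 39775/39834 records
axes: temporal PC1 explains 90.8% of variation
axes: spatial PC1 explains 70.8% of variation
axes: content PC1 explains 60.5% of variation
clusters: temporal best_k = 2, ASW = 0.554 (supported)
clusters: spatial best_k = 2, ASW = 0.519 (supported)
clusters: content best_k = 2, ASW = 0.344 (not supported)
Axes of participant behaviour
  temporal PCA (n = 146): PC1 90.8%, PC2 6.9%, PC3 2.0%, PC4 0.3%
  spatial  PCA (n = 146): PC1 70.8%, PC2 16.3%, PC3 12.9%
  content  PCA (n = 146): PC1 60.5%, PC2 26.6%, PC3 13.0%
  146 participants scored
```

One principal component dominates each group (the "axis"), and the
content clustering is unsupported (ASW 0.344 < 0.5) — participants vary
continuously rather than in discrete behavioural types.
`res$correlations` shows the axis structure: in this cohort recording
intensity correlates with log₁₀ records per participant at r = 0.70
(p ≈ 2e-22), recording potential at r = 0.57, and rarity recording
negatively at r = −0.31 — recorders who chase rarities submit fewer
records overall. `res$metrics` holds the ten metrics per participant;
`write_loadings()` / `project_axes()` place new participants on fitted
axes for cross-study comparison.

A command-line front end with verbs `simulate`, `metrics`, `axes`,
`cluster`, `run-all` and `sensitivity` is installed at
`system.file("cli", "recorder-axes.R", package = "recorderAxes")`.

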