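---
title: "Active learning for chemical-space expansion of log IE models"
author: "alspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active learning for chemical-space expansion of log IE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alspace)
```

## The problem

Nontargeted LC/ESI/HRMS screening detects thousands of chemical features
for which no analytical standard exists. Quantifying them requires a
predicted response factor, and the dominant approach is to model the
electrospray ionization efficiency on a log10 scale (log IE) from
molecular descriptors plus mobile-phase (eluent) descriptors. Such models
extrapolate poorly: prediction error grows with the distance between a
query chemical and the model's training set (its *explored space*). When
a new application domain (a *targeted space*, e.g. PFAS or natural
products) lies outside the explored space, the training set must be
expanded — but every new training chemical costs an authentic standard
and a measurement campaign, so the chemicals to label must be chosen
under a budget. That is a pool-based active-learning (AL) problem, and
this package implements and evaluates the batch strategies for it.

## The workflow

One AL campaign, as implemented in `run_campaign()`, repeats the
following loop after holding out a class-stratified test set (the
targeted space, 20% of the unexplored chemicals by default):

1. **Clean and scale** the descriptors, fitted on the *current* explored
   instances only (`clean_and_scale()`). Descriptors with near-zero
   variance (frequency-ratio cutoff 80/20 = 4 together with a <10%
   distinct-value condition) are removed, then greedy correlation pruning
   removes columns until no kept pair exceeds |r| = 0.75. The five eluent
   descriptors (pH, NH4+ presence, polarity, viscosity, surface tension)
   are protected: they bypass both filters and the correlation
   computations entirely. Cleaning is refit at every iteration because a
   descriptor that is uninformative in a small explored space can become
   informative once labeling adds variance — the filters must be allowed
   to re-admit it.
2. **Fit** the log IE regressor, an extreme-gradient-boosting tree
   ensemble (`fit_regressor()`), and — for the strategies that need an
   uncertainty signal — a quantile regression forest
   (`fit_interval_model()`), both on the scaled explored instances.
3. **Evaluate** on the held-out targeted space: per-class RMSE, pooled
   RMSE and R². The evaluation *before* the first selection is recorded
   as iteration 0, the "before AL" baseline.
4. **Select** a batch of `n_sample` chemicals from the pool with the
   configured strategy and move *all* of their instances into the
   explored set (a labeled chemical's every measured condition becomes
   training data).

Campaigns are repeated over independent splits (50 by default, matching
standard practice for this design) and summarized per iteration.

## Evaluation statistics

The unexplored space consists of several chemical classes of very
different sizes, so a plain RMSE over the test set would be dominated by
the largest class. The per-class RMSE is therefore pooled with equal
class weights:

$$\mathrm{RMSE}_i = \sqrt{\tfrac{1}{n_i}\sum (\widehat{y} - y)^2},
\qquad
\mathrm{RMSE}_{pooled} = \sqrt{\tfrac{1}{m}\sum_{i=1}^m \mathrm{RMSE}_i^2}$$

Across the $N$ repeated splits the spread of the pooled RMSE is
summarized as

$$s = \sqrt{\tfrac{1}{N}\sum\big(\mathrm{RMSE}_{pooled} -
  \overline{\mathrm{RMSE}}_{pooled}\big)^2}, \qquad
\mathrm{SEM} = s/\sqrt{N}$$

Note the denominator-$N$ (population) form of $s$; `repetition_stats()`
exposes a `sample_sd` flag for the $N-1$ convention. $R^2$ is the
squared Pearson correlation between predicted and measured log IE, the
quantity read off a predicted-vs-experimental scatter plot, rather than
$1 - SS_{res}/SS_{tot}$.

## The sampling strategies

All strategies operate at the *unique-chemical* level on the cleaned,
scaled pool; ties are everywhere broken by ascending chemical id so each
strategy is deterministic given the RNG state.

- **random** (`sample_random()`) — uniform without replacement; the
  baseline every informed strategy must beat.
- **clustering** (`sample_cluster_representatives()`) — k-means with
  k = `n_sample`; per cluster the chemical nearest its centroid. Pure
  representativeness.
- **uncertainty** (`sample_uncertainty()`) — the `n_sample` chemicals
  with the widest quantile-forest prediction intervals (defaults to the
  0.05–0.95 interval). Pure informativeness; with large batches the
  selected chemicals tend to clump in one distant region, which is
  exactly the redundancy the evaluation exposes.
- **anticlustering** (`build_anticlusters()` + `sample_anticluster()`) —
  the pool is partitioned once into K = round(pool/`n_sample`) groups of
  near-equal size that each *maximize* within-group heterogeneity, and
  one random group is labeled per iteration. Maximum within-group
  diversity and minimal between-group difference are two faces of the
  same objective: the groups end up mutually similar, each a miniature
  of the whole pool.
- **mix** (`sample_mix()`) — k-means as in clustering, then the
  cluster-level mean member-to-centroid distances are split by a second
  2-means into *sparse* and *dense* clusters; sparse clusters contribute
  their widest-interval chemical, dense clusters their centroid-nearest
  one. Requires `n_sample >= 2` (a single cluster cannot be split into
  sparse and dense).
- **cost** (`sample_cost()`) — the `n_sample` cheapest chemicals with a
  vendor price; a realism check rather than an AL strategy.

### Design choices that were genuinely open

- *Anticlusters are built once* on the initial pool and visited in a
  random permutation. Rebuilding each iteration is available
  (`rebuild_anticlusters = TRUE`) but the one-shot plan is the default:
  it is deterministic given the seed, cheaper, and consistent with the
  observation that consecutive anticluster batches stay chemically
  close.
- *The sparse/dense split operates on cluster-level means*, not on
  per-point distances. With `n_sample = 5` on a pool of four tight blobs
  and one diffuse one, exactly the diffuse cluster classifies sparse —
  the behavior the mix strategy is designed around. If all cluster means
  coincide the 2-means is degenerate and every cluster is treated as
  dense, reducing mix to clustering.
- *The exchange heuristic* for anticlustering starts from a random
  balanced partition and repeatedly applies the best cross-group swap
  (the one that most increases the sum of within-group pairwise
  distances) until no swap improves the objective or a swap budget
  (`n_exchange_passes` × pool size) is reached. On 10-point/2-group
  instances it reaches ≥95% of the enumerated optimum (all 126 balanced
  partitions); the objective is non-decreasing by construction.
- *k-means initialization*: `stats::kmeans` with 10 random restarts.
  A k-means++ seeding would also be reasonable; restarts with a seeded
  RNG give the same protection against bad local optima while keeping
  the dependency surface to base R.
- *d_NN=5 aggregates by the mean* of the five nearest-neighbor
  distances; `knn_mean_distance(agg = "median")` is available since the
  aggregator is a convention, not a law. Distances are computed at the
  chemical level from molecular descriptors only — molecular identity,
  not the eluent condition, defines neighborhood.

## Models

The point predictor is gradient-boosted regression trees (xgboost) with
fixed defaults of 300 rounds, depth 6, learning rate 0.1, single-thread
and seed-controlled; campaign simulations use a reduced 60-round,
depth-4 configuration. No hyperparameter search is performed — in an AL
loop the model is refit hundreds of times and a fixed, reproducible
configuration is worth more than a marginally better tuned one. The
uncertainty model is a quantile regression forest (ranger,
`quantreg = TRUE`, 500 trees; 200 in simulations) with the interval
level (0.05, 0.95) exposed in `campaign_config()`. Variable importance
is the total-gain share normalized to sum to one over the kept columns.

## Quantification

`fit_calibration()` fits
$\log_{10}(\mathrm{intensity}/C) = a + b \cdot \widehat{\log IE}$ on
calibrant chemicals and `predict_concentration()` inverts it; the slope
is estimated rather than fixed at 1. Accuracy is reported as the fold
error $\max(C_{pred}/C_{ref},\, C_{ref}/C_{pred}) \ge 1$, aggregated by
the geometric mean — the natural mean for a ratio-scale, symmetric error
(the arithmetic mean would be dominated by a single outlier). The
package ships a reference table (`alpinia_quant()`) of ten natural
products in *Alpinia officinarum* extract quantified by log IE models
trained before and after chemical-space expansion; on its five
referenced chemicals the geometric-mean fold error improves from 4.08×
(maximum 81.25×) to 2.94× (maximum 37.5×), the package's worked example
of why expansion matters.

## The synthetic benchmark

Real descriptor data cannot ship with the package, so `generate_space()`
builds a space with the statistical structure the analysis assumes:

- an explored space drawn from one Gaussian region of descriptor space,
  each chemical replicated over 8–17 mobile-phase conditions from a
  fixed grid (about a thousand instances at the default 81 chemicals);
- an unexplored space of 369 chemicals in 4 classes of unequal size
  (0.35/0.30/0.20/0.15) whose centers are offset by
  `class_shift × cluster_spread` in random directions, so
  unexplored-to-explored d_NN=5 distances stochastically exceed
  within-explored ones, and the offset is monotone in `class_shift`;
- a response `y = β·(informative descriptors) + class offset +
  γ·(eluent descriptors) + N(0, noise_sd²)`, linear by default so that
  noise-free parameter recovery is a closed-form test, with a
  `nonlinear` option (pairwise interaction terms) used in campaign
  simulations so tree ensembles have something to learn;
- descriptor fodder for the cleaning stage: two near-collinear copies of
  informative descriptors and two columns constant in the explored space
  but varying in the last unexplored class, which exercises both filters
  and the re-admission of a descriptor after labeling;
- per-chemical prices that are lognormal with log-mean increasing in the
  chemical's d_NN=5 to the rest of the pool — dense regions are cheap,
  so cost-based selection under-covers sparse regions — and a fraction
  (10%) of unpriced, unavailable chemicals.

Default numeric choices: `noise_sd = 0.3` log IE units (a realistic
measurement-plus-model noise scale for log-scale ionization
efficiencies), `class_shift = 6` within-class standard deviations (far
enough that the baseline model visibly fails on the pool), one instance
per unexplored chemical (a newly purchased chemical is measured once;
configurable). Simulation tests and the acceptance script run a reduced
space — 30 explored / 120 unexplored chemicals, 16 descriptors, 4–8
conditions per chemical, 20–50 repeated splits, one AL iteration — sizes
chosen so the full suite exercises every strategy end to end in seconds
while keeping the class structure and shift of the full-size default.

What the generator does *not* emulate: real PaDEL descriptor marginals
(heavy-tailed, discrete, block-correlated), real chemical class geometry
(classes are convex Gaussian blobs here), or condition-by-chemical
interactions in the response. Passing campaign tests therefore
demonstrate that the machinery behaves as designed under the assumed
geometry — a separation between explored and unexplored spaces that AL
can close — not that any particular RMSE level will be attained on
measured data.

## Degenerate inputs and numerical conventions

- Standard deviations use denominator n−1 (scaling) except the
  repetition spread s (denominator N, above). Quantiles are linear
  interpolation (type 7).
- A protected column with zero variance gets scale 1, never 0.
- Squared-distance cancellation in `pairwise_euclidean()` is clamped at
  zero before the square root.
- `split_targeted_space()` allocates the test quota across classes by
  largest remainder (369 chemicals at 0.2 give a 296/73 split); a class
  with fewer than 2 chemicals triggers an unstratified fallback with a
  warning.
- Pool exhaustion raises a typed `pool_exhausted` condition; campaigns
  catch it and truncate with a flag instead of failing.

## Known limitations

- The uncertainty signal is an interval width, not a calibrated
  variance; its coverage is only loosely tested (≥80% for the 90%
  interval in-distribution).
- Anticlustering optimality is heuristic; only small instances are
  verified against enumeration.
- The space-separated cross-validation rotates single classes as the
  explored space; other pairings (unions of classes) must be constructed
  by the caller.
- Quantification assumes one global response-factor calibration; matrix
  effects and per-class calibrations are out of scope.
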