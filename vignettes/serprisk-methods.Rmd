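---
title: "Methods: enumeration-area snakebite risk indices, travel time and cluster profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enumeration-area snakebite risk indices, travel time and cluster profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serprisk)
```

## Overview

`serprisk` implements an enumeration-area (EA) scale risk analysis for
snakebite envenoming. The pipeline has five analytical stages, each a
module with its own functions, plus a synthetic-data generator that makes
the whole chain testable end to end without any external data:

1. **Species richness** — per-species habitat-suitability surfaces are
   binarized at thresholds maximizing sensitivity + specificity and
   summed into a venomous-species richness layer.
2. **Risk indices** — four composite indices (hazard, exposure,
   susceptibility, healthcare resource scarcity) built by ranking each
   EA's cosine similarity to a hypothetical worst-case reference.
3. **Healthcare access** — minutes of travel to the nearest treating
   facility over a friction surface, by exact multi-source Dijkstra.
4. **Risk profiling** — seeded k-medoids clustering of EAs on the index
   scores, scored by the Calinski-Harabasz pseudo F-statistic.
5. **Registry statistics** — tabulations, relative risk with census
   denominators, chi-squared with Cramér's V, and a log-linear
   elevation-incidence rate fit.

## The worst-case cosine-similarity index

Each index is defined by a set of oriented EA variables
(`default_variable_specs()`). The pipeline of `similarity_rank_index()`:

1. z-standardize every variable: subtract the mean over EAs, divide by
   the standard deviation. The **population** sd (divisor $N$) is the
   default; the choice is configurable and never changes ranks, because
   a common positive rescaling of a column rescales both the EA values
   and the reference identically.
2. Build the worst-case reference: the column maximum for
   higher-is-worse variables, the minimum for lower-is-worse ones,
   standardized with the same means/sds.
3. Score each EA by the cosine similarity
   $\sum_i A_i B_i / (\lVert A\rVert\,\lVert B\rVert)$ of its
   standardized row $A$ against the standardized reference $B$.
4. Rank EAs from 1 (most similar to the worst case) to $N$, and map
   ranks linearly to $[0,1]$: score $=(N-\mathrm{rank})/(N-1)$.

Design choices made where the method description was open:

* **Rank-based normalization.** "Normalized to 0–1" could mean min-max
  scaling of the similarity values or of the ranks; ranks were chosen
  because the result is invariant to the (arbitrary) spacing of cosine
  values and guarantees the endpoints are attained.
* **Tie handling.** Ties in cosine similarity are broken by Euclidean
  distance to the reference (nearer = riskier), then stably by EA id.
  The distance tie-break matters only in degenerate geometries — most
  importantly the single-variable index, where 1-D cosine collapses to
  the sign of the z-score: with the distance tie-break, a
  single-variable index orders EAs exactly by the raw variable in its
  risk orientation, which is the behaviour a scarcity index built from
  travel time alone must have.
* **Hazard combination.** Hazard is "a function of" species richness
  and reported bite counts; it is realized as the same two-variable
  similarity index rather than a product, keeping all four indices
  methodologically uniform.
* **Missing values** exclude an EA from that index with a warning; no
  imputation.

## Species richness

`vif_stepwise()` removes, one variable per iteration, the covariate with
the largest variance inflation factor $\mathrm{VIF}_j = 1/(1-R^2_j)$
while it exceeds 10 (the `vifstep` convention); exact collinearity is an
infinite VIF, and constant columns (undefined VIF) are dropped first
with a warning. `max_sss_threshold()` searches the unique pooled
presence/background scores and returns the **smallest** threshold
maximizing sensitivity + specificity; classification is presence when
score ≥ threshold (closed on the presence side), making maps maximally
inclusive under ties. Cell richness is the count of species whose
suitability meets their threshold; nodata in any layer propagates.

## Travel time

`build_friction_surface()` assigns every cell a speed: the road speed
where a road is present, otherwise the landcover-class speed, times
`slope_penalty^(slope in degrees)` (default 0.97/degree), floored at the
walking floor speed (default 1 km/h). Water/protected cells act as a
barrier class: walking floor by default, impassable optionally.
Friction is $60/(\text{speed}\cdot 1000)$ minutes per metre.
`travel_time_surface()` runs exact multi-source Dijkstra on the
8-connected lattice with edge cost = centre distance (cell size, or
$\sqrt2\times$ diagonally) × the **mean** of the two endpoint frictions;
the mean keeps the cost symmetric and the metric admissible. On uniform
friction the computed time is between 1 and $\approx 1.0824$ times the
straight-line cost, the octile-metric bound. Per-EA travel time is the
unweighted mean by default (whether the source analysis
population-weighted it is unstated); a population raster enables
weighting.

## Risk profiling

`assign_seeds()` seeds one medoid per index with that index's rank-1 EA;
a taken EA falls through to the index's next rank, and when more
clusters than indices are requested (the default four-cluster solution
from three risk indices) the indices are cycled through deeper ranks.
`kmedoids_partition()` alternates nearest-medoid assignment with
within-cluster medoid recomputation until labels stabilize, then applies
a greedy PAM swap phase (best improving medoid/non-medoid exchange,
re-alternating after each accepted swap). The objective — total
Euclidean distance of EAs to their medoids — decreases weakly at every
step and the result is fully deterministic given the seeds; on small
instances the swap phase attains the exhaustive-search optimum, which
the tests verify at $n=8$ against all $\binom{8}{2}$ medoid pairs.

Cluster quality uses the Calinski-Harabasz pseudo F-statistic
$(R^2/(n_c-1))\,/\,((1-R^2)/(n-n_c))$ with $R^2 = 1-\mathrm{SSW}/\mathrm{SST}$
pooled over variables; the per-variable $R^2_k$ decomposition is
returned alongside. Perfect separation (SSW = 0) is flagged degenerate.
The two analyses are `run_analysis(indices, include_scarcity = FALSE)`
(bite risk: hazard, exposure, susceptibility) and
`include_scarcity = TRUE` (outcome risk, adding travel time), both with
4 clusters by default and an optional pseudo-F sweep over candidate
counts.

## Registry statistics

`poisson_elevation_fit()` maximizes the Poisson log-likelihood of per-EA
counts with log link, $\log\mu = \alpha + \beta\,(\text{elev}/100) +
\log(\text{person-years})$, by iteratively reweighted least squares
(convergence: coefficient change < 1e-8, max 50 iterations), and reports
$\beta$, its information-matrix SE, and the percent change per 100 m,
$100(1-e^\beta)$, with a delta-method SE. A Poisson fit deliberately
stands in for a negative-binomial one: the recovery target is the rate
coefficient, the synthetic generator is conditionally Poisson, and no
dispersion parameter is needed; with mild extra-Poisson variation
(archetype rate effects) the model SE slightly understates the sampling
variance. Relative risks use census denominators with the log-scale CI
$\exp(\ln RR \pm 1.96\sqrt{1/a - 1/P_a + 1/b - 1/P_b})$; Cramér's
$V=\sqrt{\chi^2/(n(\min(r,c)-1))}$ accompanies every chi-squared test.

## The synthetic mini-country

`landscape_config()` fixes the stated world; the defaults are the
conditions the analysis assumes, chosen once:

* **Grid** 120×120 cells at 500 m (a ~60×60 km mini-country; the full
  pipeline runs in seconds).
* **Elevation** spans exactly 71–1499 m (the recorded bite-elevation
  span), west-high to east-low with a smooth seeded noise field
  (relative amplitude 0.15; amplitude 0 gives a strictly monotone
  gradient).
* **~400 EAs** as rectangular blocks (real national census frames run to
  thousands of EAs; EA count is a free parameter here, scaled down for
  speed). Block tiling, without the irregular shapes of real census
  EAs, keeps zonal statistics exactly enumerable in tests; the optional
  "mild merging" of blocks was dropped because the EA count must be
  exact for the examples and geometry is not load-bearing anywhere.
* **Four archetypes** — urban (10%), peri-urban (20%),
  commercial-agriculture/protected (15%), rural-poor (55%) — with
  covariate profiles encoding the cluster semantics reported for the
  study area: urban EAs have very high exposure (built-up cover,
  building density) and very low susceptibility; peri-urban EAs low
  exposure but frequent reported bites; commercial/protected EAs
  moderate exposure (large crop/tree estates) and near-zero case counts
  (populations of hundreds, not thousands); rural-poor EAs very high
  susceptibility (poverty 0.70 ± 0.04, firewood 0.85, candle/paraffin
  0.70). Landcover is painted per EA block consistently with its
  archetype (compact built-up cores, homogeneous estates, fine
  peri-urban mosaics), so fragmentation metrics agree with the drawn
  covariates.
* **Elevation-stratified archetype allocation.** Archetype counts
  follow the configured mix inside each elevation stratum, so every
  archetype's elevation distribution matches the landscape's. This is
  what makes the planted elevation effect identifiable by an
  elevation-only fit: without it, a single realization's spatial
  clustering of (say) urban EAs on the high plateau confounds the
  archetype rate effects with elevation.
* **Case rates.** Per-EA counts are Poisson with
  $\log \text{rate} = \log(\text{baseline}) + \text{archetype effect} +
  \log(1-0.038)\cdot \text{elev}/100\,\mathrm{m}$. The planted 3.8%
  decline per 100 m is the field-reported elevation effect for the
  emulated setting. The baseline (0.5 cases/1000 person-years at 0 m)
  with a national-scale population (~1.1 M across the EAs) reproduces
  a registry scale of ~930 cases over the two-year window.
* **Case attributes** are drawn independently from categorical tables
  encoding the reported case mix: 30% of bites in the 18:00–22:00
  window, January-peaking summer-heavy months, 55%/45% male/female,
  realistic age-band and occupation distributions, 55% cytotoxic
  syndromes, 66% any first aid (83% of those a tourniquet), antivenom
  in 200/932 with vials from a truncated geometric on 1–25 tuned to
  mean 5 (only the mean and range are reported), 93% recovery. The
  exact month-by-month shape is free (only the January peak is
  documented); weak attribute associations are not planted.
* **Facilities**: 20 treating facilities, placed with weights 10:5:1:1
  across urban : peri-urban : commercial : rural EAs, reflecting the
  concentration of treating facilities in and near towns.

What a green test does and does not establish: the generator emulates
the *statistical structure* the analysis assumes (archetype-separated
covariates, elevation-dependent Poisson rates, configured categorical
case mixes, urban-weighted facilities), not real geography — no
irregular EA polygons, no road-network topology, no spatial
autocorrelation beyond block archetypes and smooth fields, and
attribute independence given the EA. Passing recovery tests show the
estimators are correct for data meeting their assumptions, not that the
study's data meet them.

## Numerical conventions

* Deterministic seeding: every generator derives an independent child
  stream from the master seed, so outputs are bit-identical across runs
  and invariant to call order; replicate registries on one landscape
  use explicit replicate streams.
* z-standardization refuses constant columns by name; richness
  comparisons are closed (≥ threshold); the maxSSS tie-break takes the
  smallest optimal candidate; k-medoids swaps require an objective
  improvement > 1e-12 to accept, guaranteeing termination.
* IRLS convergence is measured on the coefficient max-change (1e-8);
  the two-group design reproduces the closed-form rate ratio to 1e-8.

## Known limitations

* **Archetype recovery by clustering is weaker than planted.** With
  registry-realistic counts (~2 expected cases per EA), the hazard
  index is dominated by Poisson noise, and the cosine transform scores
  *direction*, not magnitude, of the standardized profile — EAs that
  are "moderately bad on everything" and "moderately good on
  everything" can receive similar scores, so the moderate archetypes
  (peri-urban, commercial/protected) overlap in index space. Even a
  nearest-centroid classifier given the true archetype centroids stays
  well below an adjusted Rand index of 0.7 on the default landscape;
  the corresponding acceptance check is therefore expected to fail and
  is retained unmodified as a faithful record of this limit.
* The resolution-harmonization question (niche models at ~5 km,
  national mapping at EA scale) is resolved by requiring a single
  shared grid for all layers.
* The "proximity of reported incidents to the nearest 1%" step in the
  source hazard description is ambiguous and not implemented.
* Travel time uses a desk-scale friction surface, not national
  transport-network data; motorised vs walking scenarios are two
  `speed_table()` configurations, not a per-person mode choice.
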