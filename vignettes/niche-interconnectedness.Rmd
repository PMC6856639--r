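---
title: "Quantifying and relating three niche types in plant-pollinator communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and relating three niche types in plant-pollinator communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheweb)
```

## Overview

`nicheweb` implements a complete analysis chain for bipartite
plant-flower-visitor communities sampled along environmental gradients at
two spatial scales. Three niche types are quantified per taxon, the
covariation among the resulting ten indices is summarized as a weighted
correlation network, and the environmental assortment of interactions is
tested against a fixed-margin null model. This vignette documents the
underlying models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data tests do and do not
establish about real field data.

## The three niche types

**Realized Grinnellian niche (environment).** Every site carries a mean
seasonal soil temperature (the arithmetic mean of its logger series) and
an aspect folded onto a 0-180 degree north-south axis (east and west both
map to 90). Both dimensions are range-standardized to [0, 1] *within each
spatial scale's site pool*, so local (microclimatic) and regional
(elevational) analyses each use their own gradient as the frame of
reference. A taxon's occupancy is encoded as a *weighted cloud*: the
standardized environment row of site *p* is entered `a_pj` times, where
`a_pj` is the taxon's abundance there - plant abundance is percent cover
times 100, rounded to the nearest integer (halves away from zero, since
only "round to the nearest integer" is specified); animal abundance is
the number of interactions observed at the site. Zero-abundance sites
contribute no rows, and a rounded abundance of zero marks absence.

**Fundamental Eltonian niche (phenotype).** One row per phenotyped
individual; insect individuals of all species pooled into a family enter
together. Traits are range-standardized to [0, 1] across the pooled
individuals of the trophic level (again per scale) before any geometry is
computed - without this, Euclidean distances in trait space would be
dominated by body length, which is an order of magnitude larger than
nectar dimensions in millimetres.

**Position, marginality, volume.** Both cloud types share one code path.
The position `J` is the column mean of the cloud (replication encodes the
abundance weighting); the pool centroid `c` is the *unweighted* mean of
the taxa's positions - the pool is a set of taxa, not of individuals, so
each taxon counts once regardless of abundance (the alternative, the
centroid of the pooled cloud, would let a single hyper-abundant taxon
drag `c`); marginality `M_j = ||J - c||`. Volume uses dynamic range
boxes: for quantile level alpha, the per-dimension occupied length is
`(Q_{1-alpha} - Q_alpha) / (hi - lo)` with linear-interpolation quantiles
(R type 7), clipped to [0, 1]; lengths aggregate across dimensions by
arithmetic mean (the package's stated standard setting; product
aggregation is available via `range_box_config()`), and the volume is the
mean over the default grid alpha = 0, 0.05, ..., 0.5. Global ranges
default to the pooled per-dimension ranges of all clouds of the trophic
level. Useful anchors: a point mass has volume exactly 0; a uniform
sample spanning the full range converges to `mean(1 - 2 alpha) = 0.5`; a
degenerate pooled dimension contributes length 0.

**Realized Eltonian niche (network role).** From the aggregated
animals-by-plants count matrix (margins `A_i`, `A_j`, total `m`,
proportions `p'_ij = a_ij / A_i`, availability `q_j = A_j / m`):

* degree, species strength `sum_j a_ij / A_j`, partner diversity
  `-sum_j p'_ij log p'_ij` (natural log);
* betweenness and node specialization index (NSI, the mean shortest-path
  length to same-level taxa) in the *unweighted* one-mode projection
  (taxa linked iff they share a partner) - the definitions involve only
  shortest paths, so no weighted variant is used. Betweenness is
  normalized by `(n-1)(n-2)/2` and set to 0 for n < 3. On a disconnected
  projection NSI averages over reachable taxa only, with a warning and a
  per-taxon `reachable_all` flag; this is a package choice, since the
  index is undefined there.
* complementary specialization `d'`: the raw Kullback-Leibler divergence
  `d_i = sum p'_ij log(p'_ij / q_j)` standardized to [0, 1] between its
  feasible extremes over *integer* allocations of `A_i` interactions.
  The maximum concentrates all interactions on the partner with the
  smallest `q` - exact, because a convex function is maximized at a
  vertex of the allocation simplex. The minimum is found by greedy
  marginal allocation (one interaction at a time to the cheapest
  partner), which is exact for a separable convex objective; both are
  verified against exhaustive enumeration for `A_i <= 12` and up to 4
  partners. `d' = 0` whenever max = min (e.g. a single partner taxon).

## Interconnectedness

The ten indices (2 environmental + 2 trait + 6 network) form one matrix
per trophic level and scale; taxa missing a niche type (e.g. a plant
never surveyed in the vegetation plots) keep `NA` and correlations are
computed pairwise-complete. Pearson's r with two-sided t-based p-values
(alpha = 0.05, uncorrected - the analysis is descriptive, and the
threshold is configurable) defines the edge set; edges are weighted by
r-squared with the sign kept as an attribute.

**Modularity.** The correlation networks have exactly 10 nodes. For
graphs of at most 8 vertices `modularity_partition()` finds the global
optimum of Newman's weighted modularity by exhaustive search over set
partitions; above that it uses greedy agglomeration (merge the pair of
connected communities with the best gain, keep the best partition along
the full merge path) followed by a Kernighan-Lin-style refinement that
moves single nodes and node pairs while modularity improves. Greedy
agglomeration alone can land in local optima even on small graphs, which
is why the exact branch exists; the greedy branch is tested on graphs
with analytically known optima.

**Integration.** The variance of the eigenvalues of the (full)
correlation matrix; missing pairs are imputed as 0 only here, because
eigenvalues need a complete matrix - they are never imputed in the
network. The population variance is used, which makes the identity
`Var(lambda) = (N - 1) x mean off-diagonal r^2` exact. Because the
expected squared sample correlation of independent variables is about
`1/(n-1)`, the sample-size-corrected integration subtracts
`(N-1)/(n_eff-1)` (n_eff = median pairwise sample size), floored at 0.
This correction makes pure-noise matrices average approximately 0, which
is property-tested; it is a standard correction of this form, not a claim
of bit-identity with any particular prior implementation.

Cross-scale coupling is summarized per index by the Pearson correlation
over taxa present at both scales (reported as t, df = n - 2, p,
r-squared), and the influence of sampling intensity by correlating each
index with the taxon's total interaction count.

## The edge-length null model

Each interaction (i, j) is an edge of length `E(i, j)`, the Euclidean
distance between the partners' positions in the standardized Grinnellian
space. The statistic is the interaction-weighted mean
`<E> = sum a_ij E(i, j) / m`. The null distribution comes from random
two-way tables with the observed row and column sums, drawn by
Patefield's algorithm (`stats::r2dtable`, which implements exactly this
sequential conditional-hypergeometric scheme); taxon positions are held
fixed under the null because they derive from site-level occupancy, not
from partner identity. The one-tailed p-value uses the add-one estimator
with a weak inequality, `p = (1 + #[<E_e> <= <E_r>]) / (1 + n_sims)`:
it can never be exactly 0, and counting ties as extreme is the
conservative reading of "shorter than expected". The default
`n_sims = 10000`; at that size the strict-versus-weak choice is
immaterial in practice. The aggregated matrix is randomized, not the
per-site matrices.

## The synthetic community generator

No raw tables of this study type are publicly deposited, so the
downstream stages are exercised on a generator whose defaults *are* the
study conditions and whose ground truth is known:

* **Sites.** 8 regional sites spanning 5-15 degrees C of mean seasonal
  temperature (evenly spaced, site noise sd 0.3) and 30 local plots
  spanning 8-12 degrees C; aspect uniform on [0, 180] at both scales.
  These mirror an alpine design: an elevational gradient of roughly
  1400 m (about a 10-degree span of seasonal soil temperature) and a
  single microclimatically heterogeneous meadow.
* **Taxa.** 12 plant species and 8 insect families (2 species each) by
  default; Gaussian niche responses with optima spread along the
  gradient, breadths 3 degrees C and 60 degrees aspect - broad enough
  that most taxa occupy several sites, narrow enough that the pool
  contains clear specialists, which is what alpine cover data look like.
  Plant covers are emitted Braun-Blanquet-style (counts of 10 and 50
  become the codes "r" and "+"); insects get pollen-load categories with
  one family below the "mean category > 1" pollinator threshold, so the
  filter and the family pooling are always exercised.
* **Interactions.** A pair (i, j) receives rate
  `A_i x A_j x exp(-theta D_env(i, j)) x exp(-gamma |proboscis - nectar depth|)`,
  where `D_env` is the distance between the taxa's standardized
  environmental optima; `total_interactions` events are allocated by one
  multinomial draw and spread over sites in proportion to the per-site
  co-occurrence products `a_pi a_pj` (so per-site margins sum to the
  aggregate margins exactly). The rate is defined at the pair level
  rather than summed from per-site products deliberately: with
  `theta = gamma = 0` the cell probabilities then factorize into row and
  column propensities, which makes interactions genuinely
  environment-independent *and* makes the Patefield conditional
  distribution exactly the conditional law of the data - the null model
  is correctly specified by construction, and its measured type-I error
  is a meaningful calibration. A per-site product formulation would leak
  environmental signal through spatial co-occurrence even at theta = 0.
  Defaults theta = 2 (moderate assortment, on a space of diameter
  sqrt(2)) and gamma = 0.3 per mm.
* **Randomness.** Everything flows from one master seed through the
  documented substream rule `(seed + 1000003 k) mod (2^31 - 1)`, so each
  stage is reproducible independently of the others.

**Calibration and power conditions.** The type-I calibration runs the
generator with *both* kernels off (theta = gamma = 0) - a trait-matching
kernel breaks the factorization just as the environmental one does - on
500 datasets of 8 plants x 6 animal taxa, 8 sites and 400 interactions,
with 500 null tables each, and checks the rejection rate at alpha = 0.05
against its 95% binomial band; positions are taken from the simulated
abundance surfaces of both trophic levels so that they are fixed inputs
independent of the drawn table. Power uses theta = 8 over 100 seeds.
These problem sizes are the package's chosen simulation design: large
enough for stable rates, small enough to re-run routinely.

## What the synthetic tests do and do not show

The generator reproduces the *structure* of field data (gradients,
Gaussian occupancy, count noise, symbolic cover codes, family pooling,
a pollen filter) but not its awkwardness: there is no observer effect,
no phenology or within-season turnover, no spatial autocorrelation of
aspect, no detection bias against small visitors, and trait variation is
Gaussian around a single mode. Passing calibration here shows the test
is exact when its assumptions hold; on real data, animal positions are
estimated from the very interactions being randomized, which couples
statistic and null weakly at small sample sizes. Real analyses should
treat marginal p-values near 0.05 with corresponding caution.

## Degenerate inputs and numerical conventions

* Range standardization of a constant dimension returns 0.5 everywhere
  with a warning; a degenerate global range contributes volume length 0.
* All-zero rows/columns of the interaction matrix are dropped with a
  warning before any role index is computed.
* Correlation pairs with fewer than 3 complete observations or zero
  variance are skipped with a warning; they are absent from the network
  and imputed as 0 only inside the integration index.
* Quantiles use linear interpolation (type 7); rounding of abundances is
  half-away-from-zero; Shannon diversity uses natural logarithms.
* Ties in the greedy d'-minimization are broken towards the
  lowest-index partner, making the allocation deterministic.

## Known limitations

* Pairwise niche-overlap fractions (dynamic-range-box `port(i, j)`) and
  kernel-density hypervolumes are out of scope; volume and marginality
  summarize each taxon alone.
* Network-level aggregates (H2', nestedness, connectance) and weighted
  one-mode projections are not computed.
* The greedy modularity branch (graphs > 8 nodes) is a heuristic; its
  result is a lower bound on the optimum, typically tight at n = 10.
* The pollen-category mean pools all individuals of a family's member
  species; a species-weighted mean is a defensible alternative the
  package does not implement.

## A minimal run

```{r example, eval = FALSE}
run <- run_pipeline(list(
  simulate = list(n_plants = 12, n_animals = 8, total_interactions = 1000),
  n_sims = 2000, seed = 1, outdir = "out"))
run
print(run$scales$regional$edge_test)
run$cross_scale$animal
```
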