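---
title: "Neutral cultural drift on interaction networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral cultural drift on interaction networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`netdrift` simulates neutral cultural transmission in a haploid population of
fixed size `N`, partitioned into `S` subpopulations (communities) that
interact over an explicit undirected network whose nodes are the
subpopulations. Each individual carries a single trait label (one locus, one
dimension of cultural variation). Time advances in synchronous steps; a step
is one round of maximal social learning, not a biological generation.

At every step, independently for each individual:

1. **Source choice.** With probability `1 - m` the individual copies from its
   own subpopulation; with probability `m` it copies from a uniformly chosen
   *network neighbour* of its subpopulation. A subpopulation whose node has
   no neighbours always copies from itself.
2. **Wright–Fisher copy.** The individual adopts the trait of a uniformly
   chosen member (sampling with replacement) of the source subpopulation *as
   it was at the previous step* — the update is fully synchronous.
3. **Innovation.** With probability `mu` the copied trait is replaced by a
   brand-new label never seen before (infinite-alleles innovation).

Subpopulation sizes never change: between-group interaction is trait
*copying*, not relocation of people. This is the natural frame for cultural
transmission — communities stay where they are, ideas move — and it keeps the
per-community drift strength constant over time. A migration model that
physically moves individuals would transiently change subpopulation sizes;
we deliberately do not implement that variant.

Within a single unstructured population this kernel is exactly the classical
haploid Wright–Fisher model: expected heterozygosity decays as
`H_t = H_0 (1 - 1/N)^t`, a trait fixes with probability equal to its current
frequency, and with innovation the equilibrium heterozygosity is
`theta / (1 + theta)` with `theta = 2 N mu`. Drift dominates innovation below
the threshold `mu_c = 1 / (2N)`; these closed forms anchor the package's
validation suite.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `N` | total individuals | — | fixed over time |
| `S` | subpopulations | — | sizes `floor(N/S)`, remainder to lowest indices |
| `m` | between-group copy probability, per individual per timestep | 0.0025 | "0.25% per timestep" |
| `mu` | innovation probability per copy event | 0 | infinite alleles |
| `timesteps` | synchronous generations | 2000 | |
| `A0` | initial distinct labels | `floor(N/S)` | see below |
| `R` | replicates | 10 | |
| `seed` | master seed | 1 | replicate seeds derived, see below |
| `k` | network connectivity | — | ring/small-world degree, or kNN neighbour count |

**Initialization.** All subpopulations start *identical*: labels
`0 .. A0 - 1` are assigned cyclically inside every subpopulation, so every
label starts at frequency as close to `1/A0` as integers allow and F_ST is
exactly 0 at `t = 0`. `A0` defaults to `floor(N/S)`, the largest value for
which an even, identical start is possible. Where several conditions with
different `S` are compared (the subpopulation-count experiment family), `A0`
is pinned to the smallest default across conditions so that all of them start
with the same richness.

## Networks

Two builders cover the study designs:

* **`build_small_world(n, k, p_rewire, seed)`** — a Watts–Strogatz graph:
  ring lattice joining each node to `k/2` neighbours a side, each lattice
  edge independently rewired with probability `p_rewire` (no self-loops, no
  duplicate edges; edge count conserved). The default `p_rewire = 0` keeps
  the pure ring: the canonical experiment families vary connectivity `k`
  on unrewired lattices. A ring-regular graph must have even degree, so odd
  `k` is reduced to `k - 1` with a warning and both values are recorded.
* **`build_spatial_knn(points, k)`** — each community is linked to its `k`
  nearest others by planar Euclidean distance (ties broken by lower index),
  and the directed relation is symmetrized *by union*: a community interacts
  with at least its `k` nearest, plus anyone who counts it among theirs.
  Union (not intersection) preserves the "at least k nearest" reading; the
  realized mean degree lies in `[k, 2k]` and is recorded.

`network_metrics()` reports mean degree, per-node degrees, connected
components and the characteristic path length (mean shortest-path length over
connected ordered pairs). Degree and path length are deliberately *both*
exposed: the qualitative claim that sparse, stretched networks retain
diversity can be read through either quantity, and they disagree only in
degenerate cases. Disconnected networks are permitted — small `k` can
disconnect a spatial graph — and simulation proceeds with components
reported; isolated nodes simply never copy across groups.

**Synthetic island points.** `generate_island_points()` places `n` points on
a closed coastline: evenly spaced angles with angular jitter, a low-frequency
radial perturbation (4 random Fourier harmonics scaled by `irregularity`),
and isotropic Gaussian jitter. Defaults (`mean_radius` 8 km, `irregularity`
0.25, `jitter` 400 m, `n` 150) emulate ~150 dispersed coastal community
locations on a small volcanic island. The pattern is a *synthetic stand-in*:
it reproduces the dispersed ring-like arrangement of coastal sites but none
of the true geography (bays, cliffs, inland sites, clustering along favoured
coasts). Measured site coordinates can be supplied via `read_points_csv()`
(`id,x,y`, planar metres). `generate_connected_island()` retries seeds until
the `k`-nearest-neighbour graph is connected, logging each retry, so presets
never silently run on a split island.

## Statistics

* **F_ST** — for each label `a`, the size-weighted between-subpopulation
  variance `sigma2_a = sum_s (n_s/N) (f_sa - p_a)^2` against the total
  term `p_a (1 - p_a)`, aggregated across labels as a ratio of sums:
  `F_ST = sum_a sigma2_a / sum_a p_a (1 - p_a)`. This reduces to the
  single-trait definition in the biallelic case and equals 1 exactly when
  every subpopulation is internally fixed. Size-weighted population variance
  (weights `n_s/N`) follows Wright's definition; equal-size presets make the
  distinction moot. When every individual carries the same label the
  denominator vanishes and F_ST is defined as 0 (subpopulations are identical
  in the only possible sense), never NaN. Other multi-allele estimators
  (e.g. bias-corrected ones) would shift absolute levels but not orderings;
  none is implemented.
* **Richness** — distinct labels in the whole population.
* **Unique-trait subpopulation count** — subpopulations holding at least one
  label found nowhere else; the rare-information retention measure.
* **Heterozygosity** — `1 - sum_a (count_a/N)^2`, the probability two random
  individuals differ; used mainly because it has exact closed-form dynamics
  and therefore powers the validation suite.

`aggregate_replicates()` gives per-timestep means with Student-t 95%
intervals by default (a percentile option exists; the band construction is a
package choice). Bands are clipped to each statistic's valid range, collapse
to the mean at `R = 1`, and are flagged degenerate there.

## Reproducibility and numerical choices

* All randomness flows from one master seed. Per-replicate / per-cell seeds
  are derived by `derive_seed()`, a multiplicative congruential jump
  (multiplier 48271, modulus `2^31 - 1`): deterministic, distinct across
  indices, documented, and logged in every manifest.
* The step kernel consumes uniforms in fixed-size blocks (one per individual
  per decision), so the stream position depends only on `(N, m > 0, mu > 0)`
  and never on branch outcomes — replicates are bit-reproducible and the
  stream is auditable against the exact oracle.
* kNN distance ties break by lower node index; duplicate coordinates are
  allowed but reported.
* Every output directory carries a JSON manifest (config echo, all seeds,
  realized network metadata) sufficient to reproduce it bit-identically with
  the same package version.

## The exact oracle

`exact_markov_distribution()` enumerates every trait-count state of a tiny
instance (innovation off), builds the one-step transition matrix analytically
from the same source-mixture + multinomial contract the simulator implements,
and propagates the initial state. On a 2x2-individual, 2-label instance the
simulator's empirical distribution over 50,000 replicates sits within
total-variation distance 0.007 of the matrix power (tested at `m = 0` and
`m = 0.1`; the acceptance bound is 0.02). This is the strongest check in the
suite because it validates the *entire joint distribution* of the kernel, not
just a moment.

## Validation summary and problem sizes

The test suite validates the simulator against quantities it does not itself
compute: the `(1 - 1/N)^t` decay (single population, and a 10-community
complete graph at `m = 9/10`, which is provably panmictic); the
fixation-richness closed form `A0 (1 - (1 - 1/A0)^S)` for isolated
communities; the innovation-drift equilibrium `theta/(1+theta)` and the
`mu_c = 1/(2N)` threshold contrast; the exact Markov oracle; and brute-force
reimplementations of all four statistics. Ordering experiments run at
N = 5000 with S = 200 (or 150 spatial) communities for 1000–2000 timesteps
and 3–5 replicates — sizes chosen so the whole suite completes on a laptop
core in a few minutes while still using the full-scale population; the
preset families keep the canonical 10 replicates.

## Known limitations

* With the identical-subpopulation start and `A0 = floor(N/S)` capped at the
  subpopulation size, every label begins in *all* communities. Global label
  extinctions are therefore slow and replicate-noisy at `N = 5000`; the
  connectivity conditions `k = 50` and `k = 120` separate cleanly in F_ST but
  only weakly in richness (their 95% bands overlap at 5 replicates), and the
  rare-trait count is essentially zero over the whole connectivity x
  interaction-rate grid — a label can only become private by dying out in 199
  of 200 communities. Meaningful rare-trait retention requires either
  innovation (`mu > 0`) or an initialization with community-specific labels,
  which the identical-start design excludes. Heatmap-style sweeps should
  therefore be read for their gradient structure, not cell-by-cell values.
* A related real effect: near-panmictic connectivity at high interaction
  rates loses *fewer* labels by a fixed horizon than moderately coupled
  communities, because unstructured drift at `N = 5000` is slower than local
  quasi-fixation plus between-community coalescence. Richness is not
  perfectly monotone along the high-`k` edge of a sweep.
* Timesteps are rounds of social learning; no demographic change, selection,
  group splitting/extinction, multi-locus traits, or overlapping generations.
* Spatial networks use planar Euclidean distance on already-projected
  coordinates: no great-circle geometry, terrain or least-cost paths.
* The F_ST estimator is the plain ratio-of-sums form above; absolute levels
  under other estimators will differ, orderings should not.

## A minimal session

```{r example}
library(netdrift)

net <- build_small_world(n_nodes = 200, k = 2, p_rewire = 0, seed = 1)
cfg <- sim_config(N = 5000, S = 200, m = 0.0025, mu = 0, timesteps = 2000,
                  R = 10, seed = 1, stat_interval = 50)
res <- run_condition(cfg, net, out_dir = "out/k2")
tail(subset(res$aggregated, statistic == "fst"))

# island communities joined to their 5 nearest neighbours
isl <- generate_connected_island(150, k = 5, seed = 42)
cfg2 <- sim_config(N = 5000, S = 150, m = 1e-4, timesteps = 2000, R = 10)
res2 <- run_condition(cfg2, isl$network)
```
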