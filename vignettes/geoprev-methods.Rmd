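---
title: "Methods: multi-scale spatial analysis of disease period prevalence"
author: "geoprev developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale spatial analysis of disease period prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoprev)
```

# The problem

Rare-disease surveillance data often arrive as a few hundred geocoded case
locations inside a catchment of millions of residents. Rates computed on fine
spatial units are unstable, so cases are aggregated — here to two nested
levels, "districts" (fine) and "zones" (coarse, administrative) — and the
period prevalence PP = 10,000 × cases / population is mapped and tested for
spatial structure. Every inference then depends on choices the analyst did not
control: whether male and female cases may be pooled, how "neighboring" units
are defined, and how much the arbitrary zonation itself (the modifiable areal
unit problem, MAUP) drives the result. `geoprev` packages that whole chain —
sex-interaction point-pattern tests, prevalence aggregation, global/local/
bivariate Moran's I, the geographical-detector q-statistic, and a
random-zonation MAUP experiment — together with a synthetic-geography
generator, because the motivating health-service data are confidential and
cannot ship with code.

All coordinates are planar meters (UTM-like). No geodesic computation is
performed; inputs are assumed already projected.

# Sex dependency: K-family tests

Whether male and female cases can be pooled is decided with second-order
summary functions of the marked point pattern:

* Ripley's K, uncorrected: $\hat K(r) = \frac{A}{n(n-1)} \sum_{i \ne j}
  \mathbf 1[d_{ij} \le r]$, with $A$ the window area.
* Cross-type K between marks $a, b$: $\hat K_{ab}(r) = \frac{A}{n_a n_b}
  \sum_{i \in a}\sum_{j \in b} \mathbf 1[d_{ij} \le r]$, and its linearized
  form $L_{ab} = \sqrt{\hat K_{ab} / \pi}$.
* Difference-K: $D(r) = \hat K_m(r) - \hat K_f(r)$.

**No edge correction is applied anywhere.** Every Monte-Carlo simulation is
conditioned on the same window and the same point counts, so the estimator's
edge bias cancels between observed and simulated curves. The cost is that the
*absolute* curves are biased relative to $\pi r^2$: for a square window of
side $L$ the exact CSR expectation of the uncorrected estimator is
$E[\hat K(r)] = \pi r^2 - 8r^3/(3L) + r^4/(2L^2)$, a 10.4% deficit at
$r = L/8$. The test suite checks the estimator against this closed form, not
against $\pi r^2$.

Two simulation nulls are available, and they answer different questions:

* **Random labeling** fixes the locations and permutes the marks (class sizes
  preserved). It is the null for Difference-K ("is either sex a random subset
  of the combined pattern?"). It *cannot* detect attraction between two
  components that share the same clusters — the labels are then exchangeable,
  so the observed statistic is a draw from its own null.
* **CSR with fixed class sizes** redraws all locations uniformly in the
  window. Under it the two components are independent, which makes it the
  attraction-sensitive null for Cross-L. The pipeline uses it for Cross-L and
  random labeling for Difference-K.

Pointwise envelopes are the rank-1 min/max of the simulated curves: with 199
simulations the pointwise exceedance probability is 1/200 per tail. Global
significance over the distance interval (default 0–80 km in 160 m steps) uses
the Diggle–Cressie–Loosmore–Ford statistic $u = \sum_k \delta(r_k)^2\,\Delta r$
with $\delta = \text{obs} - \text{ref}$ (two-sided) or
$\delta = \max(\text{obs} - \text{ref}, 0)$ (one-sided, attraction). The
reference is the mean of the simulations — each simulated curve is scored
against the mean of the *others* (leave-one-out), the observed curve against
the mean of all — because the random-labeling null has no closed-form
reference for Difference-K; a theoretical $\pi r^2$ reference is available
only for K under CSR. Every pseudo-p in the package is
$(1 + \#\text{exceedances})/(1 + n_\text{sim})$, which can never be zero.
Coincident points are legal and counted from $r = 0$.

# Period prevalence

`period_prevalence()` is exact integer arithmetic scaled per 10,000; rounding
(half-up, 2 decimals) happens only in reporting functions, never internally.
Parent-level prevalence always pools counts —
$10{,}000 \cdot \sum \text{cases} / \sum \text{population}$ — and is never an
average of child rates. Zero-population units get `NA` prevalence and are
excluded (with a warning) from all autocorrelation analyses rather than
assigned 0: 0/0 is undefined and an artificial zero would fabricate a low-low
signal. No age/sex standardization is implemented: the source material labels
some outputs "standardized" but specifies no standard population or method,
so only crude prevalence is computed.

# Spatial weights

Two dependence schemes, both row-standardized before use:

* **Queen contiguity + interaction links.** Units are neighbors iff their
  polygons share at least one boundary point (corner contact counts). Contact
  is detected by boundary-to-boundary distance with a snap tolerance (default
  1 mm), absorbing the floating-point jitter of independently computed
  tessellation edges. Explicit link lists (ferry routes joining islands to the
  mainland) are added symmetrically with weight 1 *before* row
  standardization; adding a duplicate or contiguity-implied link is a no-op.
  Links are an input file, never inferred from geometry.
* **k-nearest neighbors** (default k = 4) on area centroids; generally
  asymmetric; each row has exactly k entries. Distances are rounded to 10
  significant digits before ordering so geometrically equal distances tie
  exactly; ties resolve to the smallest `unit_id`, making the matrix
  deterministic and order-independent.

Isolates (no neighbors, no links) are kept in the weights object, flagged,
and excluded from Moran computations with a warning: synthetic geographies
may legitimately contain them even though the emulated real geography does
not after ferry augmentation. Every weights object reports its connected
component count; joining an island by a ferry link reduces it.

# Moran statistics

With $z_i = x_i - \bar x$ and $S_0 = \sum_{ij} w_{ij}$:

$$I = \frac{n}{S_0}\,\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}, \qquad
I_i = \frac{z_i}{m_2} \sum_j w_{ij} z_j,\quad m_2 = \tfrac{1}{n}\sum_k z_k^2.$$

On row-standardized weights $\sum_i I_i = n I$ exactly; the suite asserts this
to 1e-10 on random graphs. The bivariate (cross-scale) variant standardizes
both variables to mean 0 and unit *population* variance and sets
$I_i = z_{x,i} \sum_j w_{ij} z_{y,j}$; with $y = x$ it reduces algebraically
to the univariate statistic.

Inference is by permutation throughout:

* Global: full random permutations of the values over units; one-sided
  (greater) by default, matching the directional question "is there positive
  autocorrelation?"; a two-sided option exists for negative observed values.
* Local: *conditional* permutation — unit i's value is held fixed while its
  neighbors' values are drawn without replacement from the other n−1 values,
  fresh per replicate. The local pseudo-p is two-sided on $|I_i|$ because
  both positive (HH/LL) and negative (HL/LH) cluster centers matter.
* Bivariate: y is permuted over the other n−1 units while x is held fixed.

Execution is serial with a single seeded RNG stream consumed in unit order,
which gives bit-identical reruns for a given seed; no parallel backend is
used, so no per-unit stream keying is needed.

Cluster classification labels units with pseudo-p ≤ α (default 0.05) by the
quadrant of (sign z, sign lag), others NS. **No multiple-testing correction is
applied, by design**: the cluster maps are exploratory, and a flagged unit is
an unusual occurrence, not a confirmed cluster. Quadrant boundaries use
`>= 0` for "high", a measure-zero convention that only matters for exactly
centered values.

# Stratified heterogeneity: the q-statistic

$q = 1 - \mathrm{SSW}/\mathrm{SST} \in [0, 1]$ with SSW the within-stratum sum
of squares (population variances weighted by stratum size; single-member
strata contribute 0). It is invariant to affine transforms of the values and
obeys the ANOVA identity SST = SSW + SSB. Significance is assessed by
permuting stratum labels (one-sided, large q), not by the noncentral-F
approximation of the original geographical-detector software: permutation is
assumption-free and consistent with the package's other tests; the F
approximation is a possible extension.

# MAUP: random Voronoi zonations

Each replicate (i) samples n_zones district centroids without replacement,
(ii) assigns every district to the Voronoi cell of the nearest sampled
generator — containment in a Voronoi cell *is* the nearest-generator
condition, so no cell polygons are needed for assignment; distance ties break
toward the smaller generator id — (iii) dissolves, pools cases and
population exactly, and (iv) tests global Moran's I on the random-zone
prevalence with both weights schemes (queen contiguity lifted from the
district adjacency, and kNN on zone centroids). Each generator district lies
in its own cell, so all random zones are non-empty. Replicates whose
prevalence is degenerate (constant, or fewer than 3 connected zones) are
retained, flagged, and counted as non-significant. The summary reports
per-scheme significant fractions *and* the union fraction, since "significant
under either definition" is the union phrasing and the reader needs all three.

A calibration subtlety the test suite documents: with values i.i.d. on the
random-zone weights the Moran permutation test is well calibrated (≈3–5%
rejection at α = 0.05). With prevalence computed from population-proportional
cases it over-rejects mildly (≈9%), because prevalence variance scales
inversely with zone population — the values are independent but not
exchangeable. And because the experiment (faithfully to its source) reuses
one case realization across all 200 zonations, the realized fraction varies
substantially between realizations; the acceptance test therefore averages
the fraction over five independent case realizations.

# The synthetic world

The generator emulates the shape of the confidential inputs, not their
geography:

* **Districts**: Voronoi cells of uniformly random points in a convex window
  (default 300 km square; 312 districts), computed by half-plane clipping
  with a nearest-first early exit. The tessellation partitions the window to
  machine precision. Multi-component windows (an optional carved sea strip)
  get their districts per component, and `ferry_links()` proposes
  closest-centroid island–mainland links, exercising the link-augmentation
  path.
* **Zones**: k-means on district centroids (default 10 zones), with stranded
  districts reassigned along the adjacency graph until every zone is
  contiguous. Any contiguous grouping suffices: the emulated zones are
  administrative, not statistical.
* **Population**: log-normal district weights (σ = `population_dispersion`,
  default 1 — postal-geography populations are right-skewed; the emulated
  zone populations span 21 thousand to 1.1 million) converted to integers by
  largest-remainder rounding so the total (default 3,163,546) is exact, not
  approximate. Conservation invariants are exact by construction.
* **Cases**: default 511 points; district chosen proportional to population
  and location uniform within it ("proportional", the spatially unstructured
  null), or a Thomas-style parent–offspring process ("clustered":
  Poisson-many uniform parents, Gaussian displacement sd `cluster_sd`,
  resampled into the window). Sex marks are i.i.d. with
  `male_fraction = 0.467`. The emulated study's female/male percentages
  (53.1%/46.7%) do not sum to 100% under one denominator, so the male
  fraction is a free parameter rather than a resolved value.

What a green test does **not** establish: the generator has no coastline
realism, no within-district population gradients, no geocoding error, and its
sex marks are independent of location — so the pipeline's behavior on real
postal geographies with spatially structured covariates is not certified,
only its algebra, calibration, and power on the stated world.

# Numerical and degenerate-input conventions

* Boundary points in the point-in-polygon spatial join are counted once, in
  the unit with the lexicographically smallest `unit_id` — deterministic and
  order-independent. Real case centroids never sit on boundaries; synthetic
  grids can.
* Polygon "dissolve" is represented as the multipolygon of member rings
  (set-equal to the union for a tessellation); centroids are area-weighted.
  GeoJSON holes are unsupported (the generator never produces them).
* GeoJSON coordinates are written at fixed 1e-6 m precision, making
  write–read–write round trips byte-identical.
* Constant values are an error for Moran and q statistics (zero variance),
  not a silent 0 or 1.
* Window components must be convex (rectangles in practice); the Voronoi
  clipping is exact for convex windows.
* The pipeline derives one named sub-seed per stage from the master seed;
  identical configs produce byte-identical reports. The MAUP stage caches on
  a parameter-and-input hash so reruns skip its cost; other stages are cheap
  enough that general caching was judged not worth the complexity.

# Known limitations

* No inhomogeneous K, pair-correlation functions, or anisotropy; no
  distance-band/kernel/travel-time weights; no FDR/Bonferroni for the LISA
  maps (deliberate); no Getis–Ord statistics.
* Queen contiguity is O(candidate pairs × segment pairs); fine for hundreds
  of units, not tuned for tens of thousands.
* The permutation q-test and Moran tests assume exchangeability under the
  null; heteroscedastic rates on very unequal populations distort levels (see
  the MAUP section) — an empirical-Bayes or binomial-model extension would
  address this.
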