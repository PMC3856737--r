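---
title: "Multi-scale habitat models for grey-sided vole occurrence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale habitat models for grey-sided vole occurrence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volescape)
```

## The scientific problem

The grey-sided vole (*Myodes rufocanus*) is a boreal forest specialist that
has declined in managed lowland forests of northern Fennoscandia. Its
occurrence is thought to respond to habitat structure at three nested
scales: the microhabitat around a trap station (ground structure, stone
holes, tree composition), the local scale of the focal forest patch (area
of contiguous >60-year-old forest), and the landscape scale (how well a
patch is connected to other old forest, and how close it lies to stone
fields — boulder terrain whose cavities provide shelter and runways).

`volescape` implements the full analysis chain for that question as a
reusable, tested pipeline: raster patch delineation, graph-theoretic
connectivity, stone-field network components with least-cost-path
distances, station-level mixed-model selection, and plot-level
nonparametric inference with discriminant classification. Because the
original trapping and GIS layers are not public, a seeded synthetic
generator reproduces the statistical structure of the study system so every
stage runs, is testable, and can be exercised at realistic sample sizes.

## Landscape representation

Rasters are held in a minimal `grid_raster` container: a numeric matrix
(row 1 = northernmost row, the ESRI ASCII convention), a cell size in
metres, the lower-left corner of the grid, and a nodata sentinel. All
coordinates are planar metres in a local frame; cell centres sit at
`(xll + (col - 0.5) cs, yll + (nrow - row + 0.5) cs)`. There is no
geodesy — every distance in the analysis is a planar Euclidean or
cost-weighted distance. ESRI ASCII grids are the canonical interchange
format because desk-scale fixtures must be human-diffable; the writer emits
a canonical form that round-trips byte-identically.

Patches are connected components of cells with stand age strictly greater
than 60 years. Two conventions matter and are explicit arguments:

* **Adjacency.** The default is 8-connectivity (diagonally touching stands
  merge), the behaviour of the segmentation tools this kind of forest data
  comes from; 4-connectivity is available. The two differ visibly on
  checkerboard-like patterns, which is why both are exercised in the tests.
* **">60" is strict.** A 60-year-old cell does not qualify.

Inter-patch distance is the minimum Euclidean distance between boundary-cell
centres. This raster-native definition is deterministic and its error
relative to polygon edges is bounded by the cell size; it is also the
convention of the connectivity tools whose file formats the package writes
(`write_conefor_files()`). When several sampling plots fall into one patch
after (re-)delineation they are flagged and, by default, merged into a
single sampling unit with pooled counts and trap nights
(`merge_plots_in_patch()`).

## Connectivity: IIC and the area-normalized flux fraction

Habitat availability is measured with the integral index of connectivity
over the dispersal-threshold graph: patches are nodes with areas $a_i$ (ha),
and an edge joins patches whose edge-to-edge distance is at most the
dispersal threshold $d$. With $nl_{ij}$ the minimum number of links between
patches $i$ and $j$ (0 on the diagonal, $\infty$ — contributing 0 — for
disconnected pairs),

$$IIC = \frac{\sum_i \sum_j a_i a_j / (1 + nl_{ij})}{A_L^2},$$

where $A_L$ is the landscape area. Patch importance is the percentage drop
of the numerator when patch $k$ is removed (link counts recomputed on the
reduced graph), and splits into three parts:

* **intra** — the patch's own-area term $100\,a_k^2/N$;
* **flux** — both orderings of the pairs involving $k$,
  $100 \cdot 2 \sum_{j \ne k} a_k a_j/(1+nl_{kj})/N$, with link counts of
  the intact graph;
* **connector** — the remainder: the patch's stepping-stone role for other
  pairs.

The analysis' predictor is the flux fraction divided by focal patch area,
$C_k = dIICflux_k / a_k$: the intra fraction is a deterministic function of
patch area (which the analysis controls for separately), the connector
fraction does not predict colonization of the focal patch itself, and
dividing by $a_k$ removes the strong flux–area collinearity. The intra and
connector fractions are still computed — the additivity
`intra + flux + connector = dIIC` is one of the package's standing
invariants (checked to $10^{-9}$ against explicit patch deletion on random
graphs).

Numerical conventions: patches are ordered by ascending id everywhere, so
floating-point summation order — and hence every reported value — is
deterministic; landscape area cancels from all dIIC ratios and is only
needed when the absolute IIC is requested.

**What is and is not monotone in the threshold.** Adding dispersal range
can only shrink link counts, so each patch's flux term *in habitat units*
($2\sum_j a_k a_j/(1+nl_{kj})$, ha²) is non-decreasing in $d$, and so is
the landscape total of the flux percentages, which equals $200(N - S)/N$
with $S = \sum_i a_i^2$ fixed and the numerator $N$ non-decreasing. The
*per-patch percentage* is **not** monotone in general: its denominator $N$
grows too. A minimal counterexample is a hub patch 200 m from two
satellites that lie 400 m apart — between $d = 250$ and $d = 500$ m the
hub's own links are unchanged while the satellite pair gains an edge, so
the hub's flux percentage falls from $35.3\%$ to $33.3\%$. On sparse
random landscapes roughly 5% of patch-threshold steps show such dips. The
package therefore states the "connectivity increases with dispersal
distance" property in its provable forms (per-patch habitat-unit flux and
landscape-total percentage), and the test suite measures — but does not
assert — per-patch percentage monotonicity.

## Dispersal thresholds

Connectivity is evaluated at 250, 500, 1000, 1500, 2000 and 3000 m. That
range brackets published estimates of grey-sided vole movement: natal
dispersal of roughly 0.2 km, long-range adult dispersal near 3 km, and the
allometric home-range scaling implemented in
`dispersal_from_home_range()` — median dispersal $7\sqrt{A}$ and maximum
$40\sqrt{A}$ for a home range of $A$ m². For the reproducing-female home
range of 0.135 ha this yields 0.26 km (median) and 1.47 km (maximum),
which the acceptance checks reproduce exactly.

## Stone components and least-cost distances

Stone fields are chained into network components with a 1000-m link radius:
fields within 1000 m of each other (edge-to-edge, for consistency with the
patch convention) belong to one component, transitively. Components
qualify for the distance analysis when their total area strictly exceeds
100 ha. Plots in regions without stone-field coverage receive `NA`
distances — missing is never imputed.

Least-cost distances run over a per-cell cost surface. The land-cover
ordering is fixed by the biology — young clear-cuts (0–20 yr) and lakes
hinder movement, old pine forest (>100 yr) facilitates it — but the actual
multipliers are not identifiable from occurrence data, so the defaults are
round numbers preserving the ordering (hindrance 10, baseline 1,
facilitating 0.5 per metre) and are config-overridable. Accumulated cost
follows the conventional GIS semantics: Dijkstra on the 8-neighbour
lattice with the move between adjacent cells costing the mean of their
per-cell costs times the step length (cell size, or $\sqrt 2$ times it
diagonally). On uniform unit cost this reduces to metres, overestimating
true Euclidean distance by at most ~8.3% (the octile-metric bound), which
the tests verify together with an independent Bellman–Ford oracle. Plots
are represented by their transect midpoint: a single cell, matching the
per-plot scalar distances the analysis needs.

## Station-level model selection

Station occurrence (0/1) is modelled with a binomial-logit mixed model:
stations are nested in plots, and the plot enters as a Gaussian random
intercept. Fitting uses `lme4::glmer` (Laplace approximation; the
`nAGQ = 0` penalized-least-squares mode is used inside large simulation
loops, where its speed matters and sign/importance conclusions are
unchanged). The parameter count is the number of fixed effects plus one
for the random-intercept variance, and the AICc sample size is the number
of stations.

Before selection, two prefilters mirror standard practice with ordinal
inventory data:

* **Collinearity:** a greedy scan in the documented inventory order drops a
  variable when its Spearman $|\rho|$ with an already-retained variable
  exceeds 0.5. Keep-first in a fixed order makes the surviving set
  deterministic. Constant variables (undefined $\rho$) are flagged and left
  for the variance filter.
* **Low variance:** variables need sample variance of at least 1 on the
  five-class cover scale. Other codings use a scale-equivalent threshold.
  The hole-count codes (0/5/10/20/40, with 0/1/5/10/20/40 for large stone
  holes) are class *labels*, so screening happens on the class index
  1..K with threshold $((K-1)/4)^2$; proportions use their legal range
  ($1/16$), continuous measures their observed range. Screening hole
  classes on the raw labels instead would discard nearly every hole
  variable regardless of information content.

All subsets of the surviving covariates (capped at 12, i.e. 4096 models)
are fitted, ranked by AICc, and weighted by
$w_i = e^{-\Delta_i/2}/\sum e^{-\Delta/2}$. Models with $\Delta_i < 4$ are
flagged as empirically supported. Averaging is *full* (not conditional):
a variable absent from a model contributes a zero coefficient, and its
relative importance is the summed weight of the models containing it.
Non-converged or separated fits are excluded with a logged warning rather
than silently kept.

## Plot-level inference

* **Mann–Whitney U** (two-sided): exact permutation null when the combined
  sample is at most 20 without ties; otherwise the tie-corrected normal
  approximation without continuity correction, the usual reporting of the
  U statistic's normal deviate. The two branches agree within 0.02 in p at
  the boundary, which is a standing test.
* **Fisher exact** (two-sided) uses the "probability no larger than
  observed" rule with a $10^{-7}$ relative slack for floating-point ties,
  and is checked against full hypergeometric enumeration to $10^{-12}$.
* **Pearson correlations** run on transformed values: `log` adds half the
  smallest positive value when zeros occur (zero densities exist — plots
  without voles), and proportions use the variance-stabilizing
  $\arcsin\sqrt p$ (a plain arcsine is ill-scaled for proportions).
* **QDA** classifies plots with group-specific covariances and priors equal
  to relative group sizes. Leave-one-out refits the model for every held-out
  object and *recomputes the priors from the remaining objects* (a config
  switch can hold them fixed; recomputation is the default because the
  prior is part of the fitted rule). A fold whose reduced training set has
  a singular group covariance is flagged and its object counted as
  misclassified — there is no silent regularization anywhere. With groups
  of two objects this rule makes every fold singular, which is exactly what
  the hand-traced four-object test pins down.

## The synthetic generator

`synthetic_config()` holds the emulated study conditions; all randomness
derives from one integer seed, and identical config plus seed gives
byte-identical outputs.

* **Grid:** 400 × 400 cells of 50 m (20 × 20 km). A 50-m cell keeps 24
  patches spanning the published 2.6–2370 ha patch-size range inside a
  desk-scale window at ~23% old-forest cover; 25 m remains the suggested
  resolution when reading real satellite-derived rasters.
* **Patches:** organic blobs grown from seeded cells (largest first, with a
  one-cell halo so distinct patches never merge), with target areas
  log-spaced over 2.6–2370 ha. Ages are 61–140 yr; stands older than 100 yr
  are classed as facilitating old pine. The matrix holds clear-cut blobs
  (ages 0–20, 12% of the window), lakes (5%), and young forest elsewhere.
* **Stone fields:** clustered blobs (3 clusters of 4–7 fields, ~30 ha
  median) plus isolated fields, so both chained and isolated configurations
  occur. Cluster centres are seeded at forest cells: boulder terrain is
  spared from felling, so remnant old forest and stone fields co-occur
  spatially — this is also what couples the connectivity and stone-distance
  predictors the way the study system couples them.
* **Plots and occupancy:** one plot per sampled patch (23 by default), at
  the patch centroid cell. Occupancy follows
  $\text{logit}^{-1}(\beta_0 + \beta_a \log a + \beta_c \log(C + 10^{-4})
  + \beta_s(-\text{lcp}/1000))$ with defaults $\beta_0 = 27$,
  $\beta_a = 0.5$, $\beta_c = 2.5$, $\beta_s = 2.2$. The small offset keeps
  isolated patches ($C = 0$) on the scale. The coefficients were fixed once,
  by simulation, to reproduce contrasts of the magnitude the study system
  shows (occupancy near 12/23; strongly significant connectivity and
  stone-distance differences; a positive but weaker area effect). Occupied
  plots draw counts from a zero-truncated Poisson (mean 6 over 150 trap
  nights), giving densities of a few voles per 100 trap nights.
* **Stations:** ten per plot with all 26 inventory covariates drawn from
  their legal code sets. Cover variables follow realistic abundance
  profiles — a few widespread strata with real spread, many sparse ones —
  so the prefilters behave as they do on field data. Stone covers and hole
  counts shift upward near stone fields through a proximity score
  $e^{-\text{lcp}_{km}/1.5}$. Station occurrence follows
  $\text{logit}^{-1}(-4.2 + 4.5\,\text{pine} + 1.2\,(\text{LS-holes}/10)
  + u)$ with $u \sim N(0, 1)$, making pine and large stone holes the only
  active covariates (rate ≈ 0.3). Seven stations are dropped at random,
  emulating field losses and leaving n = 223.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: within-plot spatial autocorrelation of
covariates beyond the plot random intercept; measurement error and
systematic age bias of satellite-derived forest data; multi-year vole
population cycles; matrix heterogeneity beyond three cost classes; and any
real geometry of Scandinavian stone fields. The generator demonstrates that
the *machinery* recovers known effects at the study's sample sizes, not
that the effects are true in nature.

## Problem sizes and runtime choices

The default test suite runs the worked examples and property checks on
small fixtures (grids up to 25 × 25, graphs up to 12 nodes, 15 × 15 cost
surfaces with a Bellman–Ford oracle) and the full-pipeline replicate study
at the study's own sizes — 100 replicates of 23 plots / 223 stations with a
six-covariate dredge (64 mixed models per replicate at `nAGQ = 0`). The
analysis scripts use the full 12-covariate dredge (4096 models, about two
minutes) for the single study landscape.

## Known limitations

* The joint event "connectivity and stone-distance contrasts both
  significant at $p<0.05$ with 16-vs-7 groups" has a replicate-study rate
  of roughly 0.77–0.92 depending on the seed window (the two tests share a
  latent spatial factor but keep independent noise); the sign and
  direction properties hold in essentially all replicates. This is a
  small-sample power boundary, not a machinery defect.
* Patch distances are cell-centre based; on very coarse grids the
  threshold graph near the cut-off distance can differ from a
  polygon-based delineation by up to one cell size.
* QDA requires at least $p + 1$ objects per group; with seven absence
  plots, predictor sets are limited to a few variables, exactly as in the
  study design.
* The cost-surface multipliers are conventions, not estimates; conclusions
  about least-cost distances should be read relative to the stated
  ordering, and the config exposes them for sensitivity sweeps.
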