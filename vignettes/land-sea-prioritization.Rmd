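---
title: "Land-sea reserve prioritization under storm sediment risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land-sea reserve prioritization under storm sediment risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridge2reef)
```

ridge2reef chains four models into one planning workflow: storm-event
sediment export from island watersheds, a power-law turbidity plume over a
marine grid, a probabilistic model of hard-coral condition under suspended
sediment, and minimum-set marine reserve selection with either deterministic
or probability-constrained representation targets. A synthetic
island-seascape generator with a fully known data-generating process stands
in for real GIS and survey layers, so every stage of the chain can be tested
against ground truth. This vignette records the models, the defaults and why
they were chosen, and the design decisions taken where more than one
reasonable construction existed.

## The synthetic world

`generate_landscape()` builds a square grid (default 64 x 64 cells of 1 km)
holding an island in a surrounding sea. Terrain is a spectral Gaussian
random field (amplitude spectrum $|k|^{-\beta/2}$, default $\beta = 3$)
plus radial island bumps, thresholded so a configurable fraction of the
interior (default 0.3) is land; minor fragments are flooded and a two-cell
sea ring is enforced at the grid edge so all drainage terminates in the sea.
A single resolution is used for both hydrology and planning; the 1-km
default makes sea cells directly usable as planning units. Land carries four
cover classes (forest, grassland, cropland, bare) with cover-management
factors C = 0.003, 0.05, 0.2, 0.35 and base curve numbers 60, 70, 78, 86 —
mid-range values from the soil-loss literature for humid tropical
landscapes — plus a smooth erodibility field (K about 0.05-0.45) and a
cyclone-event rainfall field (250 mm base plus 0.25 mm per metre of
elevation, an orographic gradient typical of high islands).

Marine features mirror the qualitative layout of a high-island fringing
system: a mangrove fringe on coast-adjacent sea cells, patchy inshore
seagrass (1-3 cells offshore), a reef arc 3-8 cells offshore, and a few
large turtle feeding grounds overlapping seagrass and reef. That co-location
is deliberate: it reproduces the situation where one coastline section
concentrates every feature and is selected under any scenario.

Fisher opportunity cost follows the standard data-poor proxy: coastal town
populations (6 towns, log-uniform 2,000-50,000 people) spread with a quartic
(biweight) kernel, the kernel used by desktop-GIS density tools:
$f(d) = w \cdot \tfrac{3}{\pi r^2}(1 - (d/r)^2)^2$ for $d < r$. The surface
integrates back to the total population (tested to 2%); the default radius
is 10 cells. A planning unit's cost is the expected fisher count in the
cell plus a small base cost (0.1) so that empty units are never free.

All randomness flows from one base seed; the pipeline derives stage seeds
by fixed offsets (landscape +0, surveys +1, posterior draws +2, annealing
base +3), so a single integer reproduces the entire run bit for bit.

## Storm hydrology

Runoff uses the SCS curve-number method: retention
$S = 25400/\mathrm{CN} - 254$ (mm) and
$Q = (P - 0.2S)^2/(P + 0.8S)$ for $P > 0.2S$, else 0. Cell sediment yield is
the storm-event modified universal soil loss equation,

$$S = a\,(Q\,q_p)^{b}\,K\,C\,P\,\mathrm{LS},$$

with the standard metric coefficients $a = 11.8$, $b = 0.56$ as defaults
(both configurable — regional recalibrations exist and should be supplied
when known). Yields are interpreted as relative, not absolute, masses; on
that reading the peak flow $q_p$ only needs to preserve ordering across
cells, so it is the uniform-release proxy
$q_p = Q \cdot \mathrm{cellarea}/(3600\,D)$ with a default event duration
$D = 24$ h. LS is the RUSLE form
$(\lambda/22.13)^m (65.41\sin^2\theta + 4.56\sin\theta + 0.065)$ with the
length exponent tabulated on percent slope (0.5 at >= 5% down to 0.2 below
1%); slope is taken along the D8 descent direction and slope length
$\lambda$ is the longest upstream flow path plus half a cell. No slope-length
cap is applied; at 1-km cells LS is large in absolute terms, which is
immaterial for relative loads but worth knowing before comparing values
across resolutions.

Routing is D8 over a priority-flood-filled DEM. Filling raises each cell to
at most its spill elevation plus a tiny epsilon per step
($10^{-6} \times$ cell size), which guarantees a strictly descending
8-connected path from every land cell to the coast — so flow directions are
acyclic by construction, accumulation can run in topological order, and
watersheds partition the land exactly. Ties in the steepest-descent choice
break on a fixed clockwise neighbour order starting east, making the whole
stage deterministic. Watershed loads are summed straight to their coastal
pour points with no in-stream deposition and no sediment delivery ratio:
total pour-point load equals total cell yield exactly, and the tests assert
this conservation identity.

## The plume and its covariate

Pour-point loads disperse over sea cells as a power law,
$z_{ij} = \beta_j d_{ij}^{\alpha}$, summed over sources, with
$\alpha = -2.3$ by default (a value fitted for a high-island fringing-reef
coast). Distances are Euclidean centre-to-centre by default — the model
deliberately carries no hydrodynamics, so adding land-barrier routing would
overstate its realism — but an overwater metric (shortest 8-connected sea
path, via Dijkstra on the sea lattice) is available. Distances are floored
at 0.5 km (half a planning unit) to avoid the $d \to 0$ singularity; the
behaviour of the power law at the river mouth itself is not meaningful.
The coral covariate is the natural log of the summed field. Because loads
are relative, the absolute log-TSS scale is arbitrary; only its gradient
carries information, and the condition model's smooth absorbs any
shift or rescaling.

## The coral condition model

Hard-coral cover is modelled as a binomial GAM on the logit scale:
point-intercept hits out of $n$ benthic points, with a thin-plate regression
spline of log-TSS and a site-level random intercept fitted as a ridge
penalty (`s(site, bs = "re")`), using mgcv with REML smoothness selection.
REML rather than GCV is the default because the site term is a variance
component, and prediction-error criteria are known to undersmooth and
destabilize variance-component estimates; the criterion is configurable.

Surveys are simulated — and modelled — at transect resolution: three
transects of 100 points per site, one row each, rather than one pooled row
of 300 per site. The choice matters for diagnostics. A site random intercept
on one-row-per-site data is an observation-level effect: it can absorb any
extra-binomial variation, leaving the Pearson dispersion check powerless
and near-zero residual degrees of freedom. With within-site replicates, the
site effect captures between-site heterogeneity while transect-level
overdispersion (e.g. beta-binomial clumping of benthic cover) remains
visible to the Pearson $\chi^2/\mathrm{df}$ ratio, whose acceptance band
defaults to [0.7, 1.4]. The CSV exchange schema still pools to one row per
site (`site_id, x, y, n_points, n_hard_coral, log_tss` with
`n_points = 300`) for interoperability. A residual semivariogram over site
coordinates (deviance residuals averaged per site) screens for spatial
autocorrelation the TSS gradient fails to capture.

Uncertainty propagates by empirical-Bayes posterior simulation: coefficient
draws from a multivariate normal centred at the penalized fit with the
Bayesian posterior covariance of the GAM (the same construction mgcv's
`vcov()` exposes), with a symmetric-eigenvalue repair (tolerance $10^{-10}$)
guarding against numerically indefinite covariances. The per-cell
probability of good condition is the fraction of draws whose predicted
cover exceeds the 30% threshold. Predictions use the population-level site
effect (zero): off-survey cells have no site of their own, so the surface
is a statement about the median site's cover curve. The estimand it
recovers is therefore the exceedance of the population-median curve — not
the across-site exceedance rate, which is a different (wider) quantity;
the recovery tests are written against the former. The default of 1000
draws puts Monte-Carlo error on a probability near 0.9 at about 0.01.

The synthetic truth behind the surveys is linear on the logit scale: cover
`cover_clean` in the cleanest water declining by `drop_logits` across the
central (q10-q90) span of the realized log-TSS field, plus
$N(0, \sigma^2_{site})$ intercepts. Because the TSS scale is relative, the
curve's anchors are resolved once against the realized field and then
frozen, making the truth a concrete function. Defaults: cover 0.55 in clean
water, a 2.2-logit decline, site SD 0.5. These mirror the study system this
generator emulates: condition probabilities above 90% over most of the
offshore reef, low condition confined to river-mouth neighbourhoods, and a
30% good-condition threshold that is attainable — but not slack — for a 30%
representation target at 90% certainty. Choosing a lower clean-water cover
(e.g. 0.45) pushes the threshold crossing to the clean tail of the TSS
range and makes the certainty target structurally infeasible, which is not
the regime the planning comparison is about. What the generator does not
emulate: spatially correlated condition outcomes (cyclone tracks hit
neighbouring reefs together), observation error in TSS, or non-monotone
cover responses; passing tests say nothing about those.

## Reserve selection

The planning problem is the minimum-set formulation: select units
$x_i \in \{0,1\}$ minimizing
$\sum_i c_i x_i + \mathrm{BLM} \cdot \mathrm{boundary}(x) + \sum_j \mathrm{penalty}_j$,
where boundary is the exposed perimeter of the selected set. Deterministic
features pay $\mathrm{spf}_j \cdot \max(0, T_j - \mathrm{held}_j)$.

For probability-constrained features the held amount is random: each unit's
coral contributes $a_{ij}$ with probability $p_i$ (its good-condition
probability), independently across units. Under the normal approximation
($\mu_j = \sum a_{ij} p_i$, $\sigma_j^2 = \sum a_{ij}^2 p_i(1-p_i)$) the
probability the target is met is $1 - \Phi((T_j - \mu_j)/\sigma_j)$, and the
certainty constraint $\mathrm{prob}_j \ge P_j$ is algebraically equivalent
to $\mu_j \ge T_j + z_{P_j}\sigma_j$. The penalty is written in that second
form — a certainty-equivalent shortfall
$\mathrm{spf}_j \cdot \max(0, T_j + z_{P_j}\sigma_j - \mu_j)$ — rather than
as a shortfall on the probability itself, for two reasons. First, a penalty
on $P_j - \mathrm{prob}_j$ is flat (machine-zero gradient) everywhere the
normal tail underflows, so no local search can climb toward feasibility
from a sparse starting state; the certainty-equivalent form has a linear
gradient in expected held amount everywhere. Second, when every $p_i = 1$
it collapses *exactly* to the deterministic shortfall, so the probabilistic
solver with degenerate probabilities is bit-identical to the deterministic
solver under paired seeds — a reduction the tests assert. Both forms are
zero on precisely the same set of selections, so feasibility is unchanged.
The exact Poisson-binomial distribution of the held amount is implemented
as an enumeration oracle and used in tests to bound the normal
approximation's error (within 0.05 on 50-unit equal-amount instances; small
reserves of a few units are where the approximation is visibly coarse).
Independence across units is an assumed simplification; spatially
correlated impacts are out of scope and would widen $\sigma_j$.

The solver is simulated annealing over single-unit flips with geometric
cooling (default $10^5$ iterations, factor 0.999 per iteration), an
automatic initial temperature (90th percentile of $|\Delta|$ over 1000
probe flips from the random start), and a greedy improvement pass to a
fixpoint afterwards. Ensembles (default 100 runs, run $r$ seeded
$\mathrm{base} + r - 1$) yield the best solution (lowest objective, ties to
the lowest run index) and per-unit selection frequencies. Penalty factors
default to $10 \times \overline{c} / \overline{a}_j$ — a shortfall of one
average unit's worth of feature costs ten average units — so feasibility
dominates cost whenever targets are attainable; BLM defaults to 0 and
should be raised (typical useful range: the ratio of mean unit cost to
cell-side length, then up by factors of 3) when compact designs are wanted.
On 12-unit problems the ensemble recovers the exhaustive $2^{12}$ optimum
in at least 90% of random instances, which is the accuracy regime the
method is designed for; it is a heuristic, not an exact solver.

Feature targets follow the planning defaults of the emulated study: 30% of
total amount for coral, mangrove and seagrass, 10% for turtle grounds, with
the coral target probability-constrained at 90% certainty in the
cyclone-risk scenario and all features deterministic in the baseline.

## Scenario comparison

`compare_best()` scores both best solutions on a common problem, reports
areas, costs, per-feature representation and target flags, and overlap
fractions computed from a single intersection (so the two reported
percentages differ only in denominator). High-priority area sums units
whose selection frequency strictly exceeds 80%. On default synthetic
worlds the cyclone-risk design is consistently at least as large and at
least as costly as the baseline — buying certainty about coral condition
costs area and money — and the tests assert that direction (not a
magnitude, which is landscape-specific).

## Numerical and I/O conventions

Grids are matrices with square cells, row 1 at the north edge, cell centres
at origin plus (index - 1/2) times cell size; no-data is NA, and sea cells
are no-data for every hydrology layer. Rasters are exchanged as ESRI ASCII
(`.asc`), points as GeoJSON/CSV, planning problems in the Marxan file
dialect (pu/spec/puvspr/bound tables) alongside the native structures.
Every pipeline run can write a manifest of MD5 checksums; re-running an
unchanged configuration reproduces identical checksums, which is the
package's reproducibility contract.

Problem sizes used throughout the documentation and tests — 64 x 64 worlds,
72 sites x 3 x 100 points, 1000 posterior draws, $10^5$-iteration anneals,
100-solution ensembles — run in seconds on one core; they are desk-scale
choices, and every one of them scales up by configuration.

## Known limitations

- The plume has no advection, bathymetry or time dimension; TSS is a static
  relative index.
- Peak flow is a volume proxy, not a hydrograph; absolute MUSLE yields are
  not calibrated and only ordering is meaningful.
- Condition probabilities are independent across units in the solver.
- The exceedance surface is a median-site statement; site-to-site
  variability is estimated but not folded into the per-cell probabilities.
- The annealer provides no optimality certificate; for exact solutions on
  small instances use the enumeration oracle.
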