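---
title: "Switching state-space analysis of whale satellite telemetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switching state-space analysis of whale satellite telemetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whaletrackr)
```

# Overview

`whaletrackr` analyses Argos satellite tracks of migrating humpback whales
through five coupled stages: pre-filtering of raw fixes, a Bayesian
switching state-space model (SSSM) that regularizes each track to a 12-hour
grid and classifies behaviour, movement and speed metrics, occupancy-time
gridding, and bathymetric habitat comparison. Because real tag data of this
kind are rarely deposited, the package ships a ground-truthed synthetic-data
generator that emulates the statistical structure the analysis assumes, so
every stage can be exercised — and its error quantified — against known
truth.

# The movement model

## Process model

The latent track is a sequence of positions $x_t$ (longitude, latitude in
degrees) on a regular grid anchored at the whale's first retained fix and
spaced 12 h apart. Displacements follow a first-difference correlated
random walk (DCRW) whose dynamics switch with a latent behavioural state
$b_t \in \{1, 2\}$:

$$x_t - x_{t-1} = \gamma_{b_t} \, T(\theta_{b_t}) \,(x_{t-1} - x_{t-2}) + e_t,
\qquad e_t \sim \mathcal{N}_2(0, \Sigma),$$

where $T(\theta)$ is the rotation matrix through mean turn angle $\theta$,
$\gamma \in [0,1]$ is the fraction of the previous displacement carried
forward, and $\Sigma$ is an unstructured bivariate process covariance
(SDs $\sigma_{lon}, \sigma_{lat}$, correlation $\rho$). The state sequence
is a two-state Markov chain with stay probabilities $\alpha_1$ (transit)
and $\alpha_2$ (ARS). State 1 — transiting — is the fast, directionally
persistent mode; state 2 — area-restricted search (ARS) — has low
persistence, so headings become noise-dominated: reduced travel speed and
increased turning, the classical ARS signature. ARS can reflect foraging
but also resting or breeding behaviour; the model does not distinguish
among those.

## Observation model

Argos fixes arrive at irregular times with class-dependent error
(classes 3, 2, 1, 0, A, B in decreasing accuracy; Z is invalid). A fix
$y_i$ falling between grid times $t$ and $t+1$ with fractional offset
$w_i$ is linearly interpolated between the bracketing latent positions:

$$y_i = (1 - w_i)\, x_t + w_i\, x_{t+1} + \varepsilon_i,$$

with $\varepsilon_i$ t-distributed per coordinate, using a class-specific
scale and degrees of freedom. Argos supplies no error magnitudes for
location-only tags, so the defaults in `argos_error_model()` are
literature-typical values (0.3 km at class 3 through 10 km at class B,
with heavier tails for the poorer classes); both columns are
user-configurable, and none of the downstream conclusions in the test
suite depend on their precise values. Fixes arriving less than one grid
step after the last grid point extrapolate linearly on the final interval.

## Priors

The tracking literature that this model family comes from fits it in BUGS
with vague priors; we do the same, natively: $\gamma_s \sim U(0,1)$,
$\theta_s \sim U(-\pi, \pi]$, $\alpha_s \sim \mathrm{Beta}(1,1)$,
half-Cauchy(1°) on the process SDs and $U(-1,1)$ on $\rho$. These are
deliberately weakly informative; with 100+ grid points the likelihood
dominates. The track itself is anchored by a vague proper prior — first
grid position normal around the first fix, first displacement diffuse,
both with 1° SD (~111 km) — in the manner of the BUGS formulations of
this model; any real observation (class scales ≤ 0.1°) swamps it, and it
keeps the posterior proper even with no data at all, which is what makes
the prior-recovery sampler test below meaningful.

# The sampler

`fit_sssm()` runs a native Metropolis-within-Gibbs sampler (C++ core):

- **States** are drawn exactly by forward-filtering backward-sampling
  over the two-state chain, with the process density as emission (the
  first two grid points carry no emission and follow the chain prior).
- **Latent positions** use single-site bivariate random-walk Metropolis.
  Proposal scales adapt per site during burn-in only (targeting roughly
  35% acceptance), so the retained chain is a valid fixed-kernel sampler.
- **$\gamma$, $\theta$, $\Sigma$** use random-walk Metropolis ($\Sigma$ on
  log-SD / atanh-$\rho$ scale with the appropriate Jacobians).
- **$\alpha_1, \alpha_2$** are conjugate: Beta draws from the current
  state-transition counts.

The default configuration is 40 000 iterations per chain with the first
20 000 discarded and the rest thinned by 10 — exactly 2000 retained draws
per chain — with two chains started from over-dispersed parameter values
and jittered positions. Split R-hat is reported per movement parameter;
values above 1.1 trigger a warning at `regularize()` but never a failure,
since convergence is a judgement call that belongs to the analyst.

Two-state mixtures are invariant to label permutation, so draws are
relabelled post hoc to enforce $\gamma_1 > \gamma_2$: transit is *defined*
as the more persistent mode. Classification is therefore invariant to
chain initialization.

A sampler-correctness smoke test exploits the fact that with no
observations the marginal posterior of the parameters must equal the
prior: on a tiny grid the sampled $\alpha$ means are 1/2 and the
relabelled $\gamma$ means are 2/3 and 1/3 (order statistics of two
uniforms), which the test suite checks.

## Behavioural classification

The discrete state is summarized by its posterior mean $\bar b \in [1,2]$
over all retained draws of all chains (averaging across chains pools
information and is the natural estimator once chains mix; averaging
within one chain would only discard draws). Locations with
$\bar b < 1.25$ are classified transit, $\bar b > 1.75$ ARS, and anything
in between uncertain. The thresholds are applied as strict inequalities —
the boundary values themselves are uncertain — which reads the
"below/above" phrasing of the classification rule conservatively.

# Pre-filtering

Class-Z fixes are removed outright. Remaining fixes pass a speed filter
at 12 km/h, the accepted sustained-speed ceiling for humpback whales. The
filter keeps a **maximum-size** subset of fixes in which every
consecutive retained pair implies a speed at or below the threshold. We
compute that optimum exactly by dynamic programming over the
feasible-pairs graph (equivalent to exhaustive search over deletion
subsets, and verified against one in the tests). An earlier iterative
variant — repeatedly deleting the fix that resolves the most violations —
was measurably sub-optimal on about 1% of random tracks, retaining one
fix fewer than achievable, so the exact rule was adopted instead; ties
among equally large retained sets are broken towards later fixes, making
the result deterministic. The filter is idempotent, monotone in the
threshold, and applied across each whale's whole track (we do not split
by deployment gaps, which on 12-h scales are indistinguishable from
ordinary transmission gaps). Duplicate timestamps keep the most accurate
location class. Speeds use the haversine distance on a 6371-km sphere —
ellipsoidal corrections are far below Argos noise.

# Metrics

- **Minimum total distance** sums great-circle legs over the 12-h
  regularized locations; "minimum" because straight legs undercut the
  true path.
- **Mean speed** is the mean of per-segment speeds; on the regular grid
  this identically equals total distance over elapsed time (asserted in
  tests). Speeds are not estimated from fewer than 10 locations, and
  reported values are rounded half-up to 1 decimal, matching the
  formatting conventions of published tracking summaries.
- **Migration onset** is the first regularized location deeper than the
  1000-m isobath whose next 4 locations (2 days) all remain deeper. The
  published criterion also requires leaving the breeding ground
  geographically; that clause is not checkable on synthetic data, so
  onset here is purely bathymetric with the sustain rule standing in for
  "began travelling over deep water". Both the isobath and the sustain
  length are arguments.
- **Speed comparisons** use per-segment speeds as observations. The
  alternative — per-whale means — would leave error degrees of freedom
  in the low tens, inconsistent with the ~1700 error df reported in the
  study design this mirrors, which indicates segment-level observations.
  The two-factor ANOVA (category × phase) uses Type-II sums of squares
  because whale-level segment counts make designs unbalanced; with an
  empty cell the interaction is dropped with a warning, and with a
  single-level factor the decomposition reduces exactly to one-way.
  Post hoc comparisons use a hand-built Student–Newman–Keuls procedure
  on `stats::ptukey` (no SNK implementation exists in the dependency
  set), with harmonic-mean cell sizes for unbalanced groups and the
  standard containment rule; its family-wise error under the complete
  null is verified by simulation in the tests.

# Occupancy time

Locations are binned into 10 × 10 km cells drawn on a Lambert cylindrical
equal-area projection whose standard latitude is the data centroid; being
exactly equal-area, every cell covers the same ocean area at any latitude
(the tests verify $|\det J| = 1$ to within 1% across 18–37° S).
Cell occupancy is (positions × 12 h) / 24 / (distinct whales in the
cell), in days/whale; a whale revisiting a cell counts once. Cell edges
are half-open, lower-left inclusive. Consecutive residence time near a
named feature is the maximal run length of in-radius 12-h locations times
0.5 days; the association radius defaults to 50 km — the same proximity
radius used for feature summaries — because no separate value is
established for "remaining associated" with a feature.

# Habitat comparison

Depth at each location is bilinear in the bathymetry raster. Isobath
distances extract the level-set polyline by marching squares
(`grDevices::contourLines`) and take the minimum point-to-segment
distance in a local tangent plane at the query point; the nearest contour
*anywhere* is used, not the nearest within a particular feature, since
locations cannot be attributed to features without circularity. ARS
versus transit comparisons are one-way ANOVAs per covariate with
uncertain locations excluded (only the two interpretable modes are
compared); depth is reported as positive magnitude.

# The synthetic-data generator

The generator forward-simulates the same two-state DCRW the model fits —
states from the Markov chain, displacements in a local tangent plane (km,
converted to degrees with latitude-dependent longitude scaling) — then
observes it through a Poisson-thinned Argos process: irregular fix times,
location classes drawn from a configurable mix, isotropic Gaussian error
at the class scale, and corrupted class-Z fixes. Longitudes are emitted
on [0, 360) so tracks crossing the antimeridian (the study region spans
roughly 160° E–175° W) stay contiguous. Bathymetry is synthesized as a
flat abyssal floor with Gaussian seamount bumps, whose isobath ring radii
have closed forms the habitat tests check against.

Defaults were chosen once to caricature the two behavioural modes at
realistic magnitudes: $\gamma = (0.8, 0.2)$, $\theta = (0, 0)$, process
SD 0.15°/step (≈ 17 km per 12 h, giving transit speeds in the 2–3 km/h
range), stay probabilities (0.95, 0.95) (mean dwell 10 days), 8 fixes per
day, a class mix of (0.10, 0.15, 0.20, 0.20, 0.20, 0.13, 0.02) over
(3, 2, 1, 0, A, B, Z), and class error scales (0.3, 0.5, 1.5, 4, 6, 10,
500) km. Parameter-recovery checks use well-separated states
$\gamma = (0.85, 0.15)$ on 120-day tracks.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: tag failure and transmission-gap physics
(lifetime is just a duration), spatially correlated Argos errors,
movement responses to the environment (states switch independently of
bathymetry, so habitat tests construct the association explicitly by
planting seamounts under simulated ARS bouts), coastlines and land
masking, and more than two behavioural states.

# Numerical choices and degenerate inputs

- Zero time-gap fix pairs have speed $+\infty$, forcing resolution via
  the duplicate-timestamp rule (keep the best class).
- `mean_speed_kmh()` on fewer than 10 locations returns `NA` flagged
  `not-estimated` — a value, not an error; empty phase groups are absent
  from summaries rather than zero.
- Boundary classification values (exactly 1.25 / 1.75) are uncertain.
- The regular grid holds `floor(span / 12 h) + 1` points anchored at the
  first fix; a 10-day track yields 21 locations.
- Interior observation gaps of a few steps are bridged by the process
  prior (fits succeed; positions interpolate smoothly).
- Empty occupancy input yields an empty grid; cells with no visitors are
  absent by construction.

# Problem sizes used in the checks

The bundled checks run at sizes chosen to give stable statistics while
keeping a full run comfortably interactive: 120-day single-whale tracks
with 8000-iteration / 4000-burn-in / thin-5 chains for parameter
recovery (five replicate seeds), 60-day three-whale fleets at
6000/3000/5 for the habitat contrast, 200 random ≤20-fix tracks for the
speed-filter optimality suite, and 400 simulated null datasets for the
Newman–Keuls family-wise error check. The full 40 000-iteration default
remains the recommended setting for real analyses.

# Known limitations

- The observation error model is fixed per class, not estimated; with
  location-only tags this is standard but means misspecified scales
  inflate or shrink the process noise estimates.
- Behavioural states are binary; real behaviour is graded, which is why
  the uncertain band exists.
- The local tangent-plane distance used for isobath queries degrades
  slowly with distance (curvature effects at many hundreds of km), but
  at those magnitudes "distance to isobath" is no longer ecologically
  meaningful anyway.
- Each whale is fitted independently; there is no hierarchical pooling
  of movement parameters across animals.
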