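# whaletrackr

Movement-ecology toolkit for Argos satellite tracks of migrating humpback
whales. It reimplements, end to end and with a testable synthetic-data
path, the analysis pipeline used to study how whales leaving a South
Pacific breeding ground use seamounts and other shallow offshore features:

1. **Pre-filtering** — drop invalid class-Z Argos fixes, then remove fixes
   implying travel above 12 km/h (exact maximal-retention speed filter).
2. **Switching state-space model (SSSM)** — a Bayesian two-state
   first-difference correlated random walk fitted per whale by a native
   MCMC sampler, producing positions on a regular 12-h grid and a
   posterior-mean behaviour index.
3. **Behavioural classification** — posterior means below 1.25 are
   transit, above 1.75 area-restricted search (ARS), in between uncertain.
4. **Metrics** — minimum total distance, mean speeds by reproductive
   category and migration phase (onset = sustained crossing of the 1000-m
   isobath), two-factor ANOVA with Newman–Keuls post hoc tests.
5. **Occupancy time** — 10×10 km equal-area grid cells scored in
   days/whale, plus consecutive residence times near named features.
6. **Habitat** — depth and distance to the 200-m / 500-m isobaths per
   location, ARS-versus-transit one-way ANOVAs.

## The model

Latent positions $x_t$ on the 12-h grid evolve by a switching
first-difference correlated random walk,

$$x_t - x_{t-1} = \gamma_{b_t}\,T(\theta_{b_t})\,(x_{t-1} - x_{t-2}) + e_t,
\quad e_t \sim \mathcal{N}_2(0,\Sigma),$$

with the behavioural state $b_t \in \{\text{transit}, \text{ARS}\}$ a
two-state Markov chain, and irregular Argos fixes tied to the grid by
linear time-interpolation with class-specific t-distributed error. The
sampler (C++ core) combines forward-filtering backward-sampling for
states, adaptive random-walk Metropolis for positions and movement
parameters, and conjugate Beta updates for the switching probabilities.
See the methods vignette (`vignettes/whaletrackr-methods.Rmd`) for
priors, identifiability handling, and every numerical choice.

## Worked example

Simulate a small tagged fleet, filter it, fit the SSSM, and summarize:

```r
library(whaletrackr)

cfg <- sim_config(n_whales = 1, duration_days = 120,
                  gamma = c(0.85, 0.15), seed = 7)
track <- simulate_true_track(cfg, "W1")    # ground truth, 241 steps
fixes <- simulate_argos_fixes(track, cfg)  # 969 irregular Argos fixes

filt <- filter_argos(fixes, vmax_kmh = 12)
print(filt$report)
#> 969 locations received; 16 class-Z removed, 145 speed-filtered, 808 retained

fit <- fit_sssm(filt$fixes, mcmc = mcmc_config(8000, 4000, 5, seed = 11))
print(fit)
#> Switching DCRW fit: whale W1, 808 fixes, 240 grid points
#>   1600 retained draws (2 chains); max R-hat 1.046
#>   posterior means: gamma = (0.84, 0.21), alpha = (0.94, 0.88)

reg <- regularize(fit)
table(reg$mode)
#>       ARS   transit uncertain
#>        48       135        57
```

The fitted persistence pair (0.84, 0.21) recovers the simulation truth
(0.85, 0.15); the mode table shows the 12-h locations this whale spent
transiting versus in area-restricted search. `run_pipeline()` wires all
stages together — including occupancy grids and habitat ANOVAs — from a
single seeded configuration, and `inst/cli/whaletrack.R` exposes the same
thing as a command line.

The bundled reference table (`nc_tracking_summary()`) holds the published
per-whale tracking summary of 34 whales tagged off New Caledonia; for the
rows where printed mean speed equals distance/elapsed time at 1-decimal
rounding, the package reproduces the printed values exactly (for example
the 110-day, 8540-km whale at 3.2 km/h).

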