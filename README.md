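# wayvis

Visibility-driven wayfinding simulation and analysis in multilevel
buildings.

When people search for an unfamiliar destination in a multilevel building —
no map, no signage — the visibility of that destination becomes the primary
input to their decisions. wayvis is an R toolkit for studying that
relationship quantitatively. It is aimed at researchers in spatial
cognition, architectural analysis and pedestrian simulation who want a
self-contained, reproducible pipeline from building geometry to fitted
coefficient tables.

The package provides:

* **A parametric two-floor study building** (`build_building()`): perimeter
  rooms around an open corridor, one escalator up, and an upper-floor slab
  perforated by atrium voids in one of two layouts — a single *centralized*
  atrium or three *distributed* atria, both cutting exactly 288 m² of void.
  Eight destination doors, four per floor, either *entrance-forward-facing*
  (visible from the entrance through the voids) or
  *entrance-backwards-facing* (hidden by the slab).
* **A visibility engine**: ray-cast destination visibility bounded by a
  3D field of view (`destination_visibility()`), 2D isovists at eye height
  (`compute_isovist()`), and the *drift* measure — the distance from a
  vantage point to its isovist's area centroid — precomputed per navigation
  cell as a drift field (`build_drift_field()`).
* **Behavioral trajectory measures** over the analysis window from trial
  start to the first arrival at the escalator's bottom step: time to
  escalator, average vertical head movement (mean |Δpitch|), average cosine
  similarity between heading and the direction to the escalator, and
  average destination visibility, which splits trials into non-visible
  (NV, exactly zero) and visible (V) conditions.
* **Statistical models**: the three visibility-response forms — threshold
  `f(x) = a` if `x = 0` else `b`; linear `f(x) = a·x + b`; exponential
  `f(x) = a·e^{b·x}` — compared by Gaussian AIC/BIC, and linear
  mixed-effects models of the form

  ```
  PerformanceMeasure ~ AtriaType + Block + VisibilityCondition + Session + (1 | Participant)
  ```

  reported as coefficient / SE / Wald z / p / 95% CI tables with the
  random-intercept variance.
* **Two simulated agents**: a *visibility-based cognitive agent* — a
  finite-state machine that moves straight for the escalator when the
  destination is in sight and otherwise explores by steering to the
  minimum-drift visible cell, with a short-term memory that never revisits
  a zone — and a *shortest-path baseline* that A*-routes from entrance to
  destination ignoring visibility. Monte-Carlo experiments randomize only
  the initial heading.
* **Comparison metrics**: per-destination L1 differences against a
  benchmark, the agent-difference mixed model
  `DifferenceInMeasure ~ AgentType + (1 | Agent)`, spatial KDE rasters of
  paths, and dynamic time warping between trajectories.
* **Seeded synthetic generators** for the full study design (69
  participants × 24 trials, 828 analyzed upper-floor trials) with known
  injected effects, so the entire pipeline is testable end to end without
  any external data.

## Worked example

```r
library(wayvis)

env   <- build_building("centralized")
env
#> <wv_environment: centralized atria>
#>   footprint 36 x 18 m, 1 atrium void(s), total 288.0 m^2
#>   8 destinations, escalator base (24.0, 0.0)

grid  <- build_nav_grid(env, resolution = 1)
field <- build_drift_field(grid, env)
zones <- decompose_zones(env)

## one cognitive-agent trial towards a hidden (backwards-facing) door
tr  <- run_trial("cognitive", env, grid, field, "F2_bwd_L",
                 initial_heading = 0, seed = 1, zones = zones)
win <- extract_analysis_window(tr, env)
m   <- compute_measures(win, env, fov = agent_fov(), vis_stride = 5)
#> time to escalator: 21.0 s
#> cosine similarity: 0.867
#> avg destination visibility: 0.0000
```

The door is never visible on the way (visibility 0, an NV trial), so the
agent explores first and needs 21.0 s to reach the escalator — against
about 18.2 s for the same agent when a forward-facing door is in sight from
the spawn.

```r
## synthetic study at the full design, then the mixed model
meas <- generate_synthetic_measures(synthetic_design(seed = 1))
tab  <- prepare_trial_table(meas)
fit_lmer(tab, "time_to_escalator",
         c("AtriaType", "Block", "VisibilityCondition", "Session"),
         "Participant")
#> <wv_lmer> time_to_escalator ~ AtriaType + Block + VisibilityCondition + Session + (1 | Participant)  [REML]
#>                  term  Coef. Std.Err.       z        p  ci025  ci975
#>           (Intercept) 35.414    0.846  41.857 0.00e+00 33.755 37.072
#>  AtriaTypedistributed -1.257    0.929  -1.354 1.76e-01 -3.078  0.563
#>                 Block -1.936    0.229  -8.453 2.85e-17 -2.385 -1.487
#>  VisibilityConditionV -5.047    0.374 -13.494 1.71e-41 -5.780 -4.314
#>               Session  0.731    0.929   0.787 4.31e-01 -1.089  2.551
#> Group var 12.458   Residual var 28.958
```

The visibility-condition coefficient (−5.05 s) recovers the injected
effect: trials with the destination visible reach the escalator about five
seconds faster, while atria type and session are null effects — the same
qualitative structure the mixed model is designed to detect.

A command-line wrapper is installed at `inst/cli/wayvis.R` with subcommands
`build-env`, `drift-field`, `simulate`, `measure`, `fit`, `compare` and
`synth`; every subcommand takes `--seed` and archives its configuration
next to its outputs.

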