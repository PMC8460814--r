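---
title: "Visibility-driven wayfinding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visibility-driven wayfinding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wayvis studies a simple question with awkward geometry: when someone enters
an unfamiliar two-floor building looking for a particular door, how does the
*visibility* of that door — through atrium voids, past walls and slabs —
shape the path they take to the escalator? The package provides all four
layers needed to ask it quantitatively: a parametric building, a visibility
engine, behavioral measures over logged trajectories, and the statistical
models that relate them, plus a simulated cognitive agent whose only
"psychology" is a visibility-triggered switch between exploration and
exploitation.

## The environment

`build_building()` constructs a 36 m x 18 m, two-floor building. The first
floor is a ring of enclosed perimeter rooms around an open corridor; an
escalator in the corridor is the only way up. The second floor is a walkable
perimeter ring around a slab perforated by atrium voids in one of two
layouts: a single **centralized** atrium or three **distributed** atria.
Both layouts cut exactly 288 m^2 of void — that total is the one dimension
treated as a hard constraint, and the builder refuses other values unless
explicitly overridden. The footprint proportions, room depth (4 m), door
size (1 m x 2 m) and the rest of the parametrization are documented defaults
in `building_params()`, chosen to be architecturally plausible rather than
claimed faithful to any particular scene; every dimension is overridable.

Eight destination doors are placed, four per floor. "Entrance-forward-
facing" doors present their surface towards the entrance (on the far walls);
"entrance-backwards-facing" doors face away (on the entrance-side wall,
behind the fixed initial heading). Geometrically this makes forward-facing
upper-floor doors visible from the entrance through the atrium voids, while
backwards-facing ones are hidden by the slab from anywhere near the
entrance, whatever the viewing direction — the property that drives the
whole analysis.

Coordinates are right-handed and z-up, in meters, with yaw measured
counter-clockwise from +x and pitch positive upwards. The origin sits at
the building's south-west corner with the entrance at (0.5, 0); a corner
origin keeps every footprint coordinate non-negative, which simplifies the
rectangle bookkeeping throughout. Game-engine logs (y-up, left-handed) are
converted once, at the CSV boundary (`read_trajectories(dialect =
"unity")`).

## Visibility

`destination_visibility()` scores how visible a door is from a pose: a
uniform k x k grid of rays (default 10 x 10) is cast from the eye point to
the door rectangle, and the reported fraction is the share of rays that
fall inside the field-of-view cone (half-angles in yaw and pitch, plus a
range cap), approach the door from its front side, and are not intercepted
by a wall or by the second-floor slab (atrium voids are holes; glass doors
are transparent). A uniform target grid makes the fraction deterministic
and resolution-controlled; the suite checks Cauchy convergence in the ray
count. The field of view used when scoring human-style logs is not dictated
by anything in the data, so the default `observer_fov()` is a standard
16:9 desktop camera (60 degrees vertical, about 91 horizontal, 100 m range)
and is a parameter everywhere.

`compute_isovist()` computes the classic 2D isovist: the polygon of points
visible from a vantage at eye height (1.7 m), bounded by occluders and a
100 m range circle. Rays are swept at a configurable angular resolution
(default 1 degree) *plus* rays aimed just either side of every occluder
endpoint, so polygon corners are captured essentially exactly; only the
range-circle arc is approximated at the sweep resolution. **Drift**
(`isovist_drift()`) is the distance from the vantage to the polygon's area
centroid; it vanishes at the centers of open spaces and along corridor
center-lines, which is what makes it a useful exploration signal.
`build_drift_field()` precomputes drift for every walkable cell of the
navigation grid (default cell size 1 m; the sweep is coarsened to 2 degrees
there, which changes drift by far less than a cell width).

## Trajectory measures

All per-trial measures are computed on the **analysis window**: the
trajectory prefix from the trial start until the first sample within an
arrival radius (default 0.5 m — "the bottom step" is a point, so a radius is
unavoidable) of the escalator base. Four scalars are reported per trial:

* **time to escalator** — window duration in seconds;
* **average vertical head movement** — the mean *absolute* difference in
  pitch between consecutive samples. A signed mean would telescope to
  (last - first)/n and carry no information about visual search, so the
  absolute difference is the interpretation used;
* **average cosine similarity** — mean cosine between the 3D heading vector
  and the vector from the eye to the escalator base (+1 straight at it, -1
  straight away). The heading is taken to be the camera-forward vector, the
  natural reading for desktop mouse-look logs; a `heading_2d` switch
  projects both vectors to the horizontal plane instead;
* **average destination visibility** — the mean ray-cast visibility
  fraction over the window's samples (a stride parameter subsamples dense
  logs; the suite asserts stability under refinement).

Trials with average destination visibility exactly zero form the
"non-visible" (NV) condition; any positive value is "visible" (V). The
default analysis keeps all trials per condition and reports counts. An
optional `match_conditions()` subsamples the larger condition at random to
balance the design; how the original study matched its conditions is not
documented, so neither behavior is claimed canonical.

## Statistical models

`fit_visibility_response_models()` fits three response forms in visibility
x: threshold (a for x = 0, b for x > 0, solved in closed form by group
means), linear (least squares) and exponential a e^{bx} (nonlinear least
squares, initialized from the log-linear regression when all responses are
positive, else from (mean(y), 0)). Information criteria use a Gaussian
likelihood with three parameters {a, b, sigma} for every form so AIC/BIC
are comparable across forms; both criteria are reported since nothing
privileges one. `predict_form()` supports the extrapolation sanity report:
the linear and exponential forms extended beyond the observed visibility
range can predict physically impossible responses (cosine similarity above
1), which the threshold form cannot.

`fit_lmer()` wraps `lme4::lmer` and reports the conventional coefficient
table: estimate, standard error, Wald z with a two-sided normal p-value,
and 95% bounds at estimate +/- 1.96 SE. Encodings are fixed by
`prepare_trial_table()`: visibility condition with NV as reference (the
coefficient is the V-minus-NV effect), block as a 0-based numeric covariate
(the intercept then describes non-visible first-block trials), atria type
and session as two-level factors. Models fit by REML by default, with an ML
option for information-criterion comparisons. Singular fits are reported,
never silently dropped. `corrected_alpha()` implements the Bonferroni
threshold, and `significance_flags()` accepts a stricter declared threshold
(e.g. 0.001 when the correction would give 0.05/21 ≈ 0.0024).

## The agents

Both agents share the avatar's kinematics: eye height 1.7 m, forward speed
1.3 m/s, lateral/backward speed 0.6 m/s, and a perception cone of 150
degrees horizontally with a 100 m range. Three quantities the study design
leaves open are explicit parameters: the vertical opening of the 3D
perception cone (default 60 degrees), the turn rate (90 degrees/s — speeds
are specified but rotational dynamics are not), and the integration step
(0.1 s internally, poses logged every 0.2 s).

The **cognitive agent** is a finite-state machine. From the spawn state it
checks whether the destination is in sight (at least one unoccluded ray
within the cone); if so it A*-routes to the escalator base, rides the ramp,
and on top either routes to the destination (if visible) or explores. If
the destination is not in sight it **explores**: among the walkable cells
visible in its cone it steers towards the one with minimal drift, excluding
cells in zones it has already visited — zones being a convex tiling of the
walkable area (`decompose_zones()`, capped at 8 m extent so the short-term
memory operates at room scale). Ties break by distance, then cell index,
for determinism. Sighting the destination triggers the escalator move
(first floor) or the destination move (second floor); sight during an
ongoing move never re-plans. When the field of view offers no admissible
cell but unvisited zones remain, the agent reorients towards the nearest
unvisited zone rather than giving up — a documented interpretation of
"sufficiently explored", whose strict form (no unvisited zone holds a
visible cell) is recovered when that fallback finds nothing. Exhausting all
zones forces the escalator move on floor one and flags a failed trial on
floor two.

The **shortest-path agent** plans one A* route from entrance to destination
(8-connected grid, sqrt(2) diagonals, no corner cutting, Euclidean
heuristic routed through the single escalator link) and walks it with the
same kinematics, ignoring visibility entirely. For second-floor goals the
heuristic decomposes into distance-to-base plus a goal-dependent constant
on the first floor, so the expansion order — and hence the realized path to
the escalator — is identical across destinations; its time to escalator is
invariant to the destination by construction, which the suite asserts.

Monte-Carlo experiments (`run_monte_carlo()`) randomize only the initial
heading, uniformly on the circle, with destinations cycling through the
upper-floor set; the full-scale experiment takes 1600 samples per agent
type. Consecutive samples share an agent id across one destination cycle so
the per-agent random intercept of the difference model is identifiable.

## Agent-versus-benchmark comparison

`benchmark_differences()` scores each agent trial by the absolute deviation
of its time-to-escalator and cosine similarity from the benchmark of the
same destination (per-destination mean over benchmark trials; median
optional — the aggregation the original analysis used is not documented).
The differences feed `agent_difference_lmer()`, a mixed model with agent
type fixed (cognitive as reference, so positive coefficients mean the
shortest-path agent deviates more) and a per-agent random intercept.
`spatial_kde()` renders path distributions as normalized Gaussian-KDE
rasters (normal-reference bandwidth by default; bandwidth is a free choice
and is always recorded), and `dtw_distance()` provides unconstrained
dynamic time warping on horizontal positions for fine-grained pairwise path
comparison. Human and cognitive-agent KDE rasters are *not* expected to
match — the agent captures the time and directness patterns, not the
spatial distribution of paths — so tests assert raster validity, never
similarity.

## Synthetic data

The synthetic generator defines the study conditions the package is tested
under: 69 participants, 8 destinations repeated over 3 blocks (24 trials
each, 12 of them second-floor and analyzed — 828 trials in all), two
sessions, atria type varied between participants. Injected effects default
to the magnitudes the human study reports (visibility effect -4.935 s on
time, -0.025 degrees on head movement, +0.107 on cosine similarity; block
slopes -2.095 s and +0.039). Variance components are not reported at the
trial level in the source material, so the defaults (participant SD 4 s and
residual SD 5 s on time, with analogous choices for the other measures)
were chosen once to give realistic trial-to-trial scatter and are not
revisited.

Two levels exist deliberately. The *measures-level* generator draws the
per-trial table directly from the generating linear model — the right tool
for regression recovery and calibration tests, where thousands of model
fits are needed. The *trajectory-level* generator realizes the same effects
geometrically: piecewise-linear walks from the entrance to the escalator
base, meandering and slower in non-visible trials, yaw along the path with
condition-dependent jitter, pitch as a reflected random walk scaled to the
target head-movement level, sampled at 0.1 s. Walking speed is capped at
1.25 m/s; drawn times shorter than the top-speed walk saturate at the
physical bound rather than teleporting. Forward-facing trials are visible
from the spawn by construction; backwards-facing trials are non-visible at
spawn, though a meandering path can glance back at the door mid-trial and
earn a small positive average — a handful of such trials also occurred in
the human study, so they are left in.

What passing tests on this generator do and do not show: they demonstrate
that the measurement and inference pipeline recovers known effects embedded
in realistic geometry, not that real human data carries those effects. Real
logs differ in sampling rate (game engines log at ~0.02 s), in the
visibility scale (real windows average far more near-zero samples), and in
every behavioral nuance a piecewise-linear walk lacks. Reproducing the
study's human-data coefficient tables requires the deposited dataset,
ingested through the unity dialect of `read_trajectories()`.

## Numerical choices and degenerate inputs

Ray-segment intersection uses strict interior tests (t in (0, 1) up to
1e-9) so rays terminating *on* a door plane are not blocked by the wall
hosting the door, and grazing a wall's top edge does not occlude. Isovist
origins inside occluders error; zero-area door rectangles error; threshold
fits with only one visibility group are flagged degenerate; exponential
non-convergence excludes that form from ranking rather than failing the
fit set; trials that never reach the escalator raise a typed condition and
are counted, not measured. All randomness flows from explicit seeds
(per-trial seeds derive from a master seed by enumeration), and identical
configuration yields byte-identical trajectory files.

## Problem sizes

The test suite and the acceptance script verify behavior at desk scale,
chosen so the full battery runs in minutes on one core: drift fields on
1 m grids (about 680 walkable cells), 100-replicate model-identification
sweeps at n = 400, 50-replicate mixed-model recovery on the full 828-trial
design, 200 random-heading cognitive trials per facing condition for the
headline pattern, and 48-sample Monte-Carlo runs per agent type against a
10-participant trajectory-level benchmark for the difference models. The
full-scale configuration (1600 samples, 69 benchmark participants) is the
package default and runs unchanged, just longer.

## Limitations

The agent has no long-term spatial memory and no learning across trials; it
is a demonstration that a visibility-triggered exploration/exploitation
switch plus a drift field reproduces the headline behavioral pattern, not a
general pedestrian model, and neither agent is tuned to data. The zone
decomposition and the exploration fallback are design interpretations where
the source description is silent; both are parameterized and documented
above. The environment is a stylized two-floor rectangle with one escalator
— stairwells, elevators, more floors, and collision between agents are out
of scope.
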