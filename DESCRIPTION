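Package: wayvis
Title: Visibility-Driven Wayfinding Simulation and Analysis in Multilevel Buildings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how destination visibility shapes goal-directed
    wayfinding in unfamiliar multilevel buildings. Builds parametric two-floor
    environments with centralized or distributed atria, computes ray-cast
    destination visibility, two-dimensional isovists and isovist-drift fields,
    simulates a visibility-based cognitive agent alongside a shortest-path
    baseline, derives per-trial behavioral measures from pose trajectories
    (time to escalator, vertical head movement, cosine similarity to the
    escalator direction, average destination visibility), and fits the
    associated regression models (threshold, linear and exponential visibility
    response curves; linear mixed-effects models with participant or agent
    random intercepts). Includes seeded synthetic-trajectory generators for
    end-to-end testing and Monte-Carlo comparison of agents against human
    benchmarks via L1 differences, kernel density rasters and dynamic time
    warping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    MASS,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
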