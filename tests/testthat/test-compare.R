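test_that("benchmark differences are exact L1 deviations from the mean", {
  human <- data.frame(destination_id = c("A", "A", "B"),
                      time_to_escalator = c(10, 12, 20),
                      avg_cosine_similarity = c(0.8, 0.9, 0.5))
  agent <- data.frame(subject_id = c("a1", "a2", "a3"),
                      source = c("cognitive_agent", "cognitive_agent",
                                 "shortest_path_agent"),
                      destination_id = c("A", "A", "B"),
                      time_to_escalator = c(10, 12, 23),
                      avg_cosine_similarity = c(0.85, 0.85, 0.2))
  d <- benchmark_differences(agent, human)
  expect_equal(d$diff_time, c(1, 1, 3))      # |10-11|, |12-11|, |23-20|
  expect_equal(d$diff_cos, c(0, 0, 0.3), tolerance = 1e-12)
  expect_equal(d$agent_type, c("cognitive", "cognitive", "shortest_path"))
  ## an agent matching the benchmark exactly scores zero
  exact <- agent[1, ]; exact$time_to_escalator <- 11
  exact$avg_cosine_similarity <- 0.85
  expect_equal(benchmark_differences(exact, human)$diff_time, 0)
  ## missing benchmark destinations are dropped with a message
  orphan <- agent; orphan$destination_id <- "Z"
  expect_message(out <- benchmark_differences(orphan, human), "dropped")
  expect_equal(nrow(out), 0)
})

test_that("the agent-difference mixed model flags the worse agent type", {
  set.seed(1)
  n <- 60
  d <- data.frame(
    agent_id = sprintf("ag%03d", 1:(2 * n)),
    agent_type = rep(c("cognitive", "shortest_path"), each = n),
    destination_id = "A",
    diff_time = c(abs(rnorm(n, 2, 1)), abs(rnorm(n, 5, 1))),
    diff_cos = c(abs(rnorm(n, 0.05, 0.02)), abs(rnorm(n, 0.15, 0.02))))
  ## one record per agent: the random intercept absorbs agent identity
  d <- rbind(d, d)                           # two records per agent
  ## the simulated agent effect is near-degenerate in its random intercept,
  ## so lme4 may warn about a boundary fit; the fixed effect is what matters
  fit <- suppressWarnings(agent_difference_lmer(d, "diff_time"))
  row <- fit$coefficients[grepl("shortest_path", fit$coefficients$term), ]
  expect_gt(row$coef, 0)
  expect_lt(row$p, 0.001)
})

test_that("spatial KDE rasters integrate to one and find the mass", {
  meta <- list(subject_id = "S", trial_id = "T", block = 1, session = 1,
               atria_type = "toy", destination_id = "d", source = "human")
  ## all samples at one point: mode at that point
  tr <- trajectory(data.frame(t = seq(0, 2, 0.1), x = 3, y = 4, z = 0,
                              yaw = 0, pitch = 0), meta)
  r <- spatial_kde(list(tr), extent = c(0, 6, 0, 8), resolution = 0.25,
                   bandwidth = 0.5)
  expect_equal(sum(r$z), 1, tolerance = 1e-3)
  peak <- which(r$z == max(r$z), arr.ind = TRUE)
  expect_equal(r$x[peak[1]], 3, tolerance = 0.3)
  expect_equal(r$y[peak[2]], 4, tolerance = 0.3)
  ## two equal clusters split the mass evenly across the mid-plane
  t1 <- trajectory(data.frame(t = seq(0, 4.9, 0.1), x = rnorm(50, -5, 0.3),
                              y = 0, z = 0, yaw = 0, pitch = 0), meta)
  t2 <- trajectory(data.frame(t = seq(0, 4.9, 0.1), x = rnorm(50, 5, 0.3),
                              y = 0, z = 0, yaw = 0, pitch = 0), meta)
  r2 <- spatial_kde(list(t1, t2), extent = c(-10, 10, -3, 3),
                    resolution = 0.25, bandwidth = 1)
  left <- sum(r2$z[r2$x < 0, ])
  expect_equal(left, 0.5, tolerance = 0.02)
  expect_error(spatial_kde(list()), "no trajectories")
})

test_that("DTW distance matches a hand-rolled DP table", {
  a <- cbind(c(0, 1, 2, 3), c(0, 0, 1, 1))
  b <- cbind(c(0, 2, 2.5, 3), c(0, 1, 1, 1.2))
  ## exhaustive DP oracle, written independently
  n <- nrow(a); m <- nrow(b)
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  D <- matrix(Inf, n + 1, m + 1); D[1, 1] <- 0
  for (i in 1:n) for (j in 1:m)
    D[i + 1, j + 1] <- cost(i, j) + min(D[i, j], D[i, j + 1], D[i + 1, j])
  expect_equal(dtw_distance(a, b), D[n + 1, m + 1], tolerance = 1e-12)
  ## identity and warped-repetition properties
  expect_equal(dtw_distance(a, a), 0)
  expect_equal(dtw_distance(rbind(c(0, 0), c(1, 0)),
                            rbind(c(0, 0), c(0, 0), c(1, 0))), 0)
  ## symmetry
  expect_equal(dtw_distance(a, b), dtw_distance(b, a), tolerance = 1e-12)
})

test_that("Monte-Carlo runs are reproducible and labelled", {
  env <- fixture_env("centralized")
  grid <- fixture_grid("centralized")
  field <- fixture_field("centralized")
  zones <- fixture_zones("centralized")
  cfg <- monte_carlo_config(4, "shortest_path", master_seed = 7)
  r1 <- run_monte_carlo(cfg, env, grid, field, zones = zones)
  r2 <- run_monte_carlo(cfg, env, grid, field, zones = zones)
  expect_length(r1, 4)
  expect_identical(lapply(r1, function(t) t$samples),
                   lapply(r2, function(t) t$samples))
  ## destinations cycle through the second-floor set
  expect_equal(vapply(r1, function(t) t$meta$destination_id, character(1)),
               c("F2_fwd_L", "F2_fwd_R", "F2_bwd_L", "F2_bwd_R"))
  expect_true(all(vapply(r1, function(t) t$meta$source, character(1)) ==
                    "shortest_path_agent"))
})
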