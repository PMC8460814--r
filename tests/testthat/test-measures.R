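## toy scene: entrance at (0.5, 5), escalator base 13 m further along +x
measure_env <- function() {
  toy_env(walk1 = list(c(0, 0, 20, 10)), entrance = c(0.5, 5),
          base = c(13.5, 5))
}

straight_walk <- function(speed = 1.3, dt = 0.01, t_end = 12,
                          yaw = 0, pitch = 0) {
  tt <- seq(0, t_end, by = dt)
  data.frame(t = tt, x = 0.5 + speed * tt, y = 5, z = 0,
             yaw = yaw, pitch = pitch)
}

meta0 <- list(subject_id = "S1", trial_id = "T1", block = 1, session = 1,
              atria_type = "toy", destination_id = "toy",
              source = "synthetic")

test_that("analysis window ends at the first arrival at the bottom step", {
  env <- measure_env()
  tr <- trajectory(straight_walk(), meta0)
  win <- extract_analysis_window(tr, env, arrival_radius = 0.5)
  ## (13 - 0.5) / 1.3 s of walking to enter the arrival disc
  expect_equal(max(win$samples$t), 12.5 / 1.3, tolerance = 0.011)

  ## a path that enters the arrival disc, leaves, and comes back: the
  ## window still ends at the FIRST crossing
  xs <- c(seq(0.5, 13.2, by = 0.13), seq(13.2, 11, by = -0.13),
          seq(11, 13.4, by = 0.13))
  s2 <- data.frame(t = seq_along(xs) * 0.1, x = xs, y = 5, z = 0,
                   yaw = 0, pitch = 0)
  tr2 <- trajectory(s2, meta0)
  win2 <- extract_analysis_window(tr2, env, 0.5)
  expect_equal(nrow(win2$samples), which(xs >= 13.0)[1])

  ## never reaching the base flags an incomplete trial
  short <- trajectory(straight_walk(t_end = 3), meta0)
  expect_error(extract_analysis_window(short, env, 0.5),
               class = "wv_incomplete_trial")
})

test_that("constant pitch gives zero vertical head movement", {
  env <- measure_env()
  d <- toy_dest(cx = 20, cy = 5, nx = -1, ny = 0)
  tr <- trajectory(straight_walk(pitch = 7), meta0)
  win <- extract_analysis_window(tr, env, 0.5)
  m <- compute_measures(win, env, d, vis_stride = 20)
  expect_equal(m$avg_vertical_head_movement, 0)
})

test_that("cosine similarity attains +1 towards and -1 away", {
  env <- measure_env()
  d <- toy_dest(cx = 20, cy = 5, nx = -1, ny = 0)
  toward <- trajectory(straight_walk(yaw = 0), meta0)
  win <- extract_analysis_window(toward, env, 0.5)
  m <- compute_measures(win, env, d, heading_2d = TRUE, vis_stride = 50)
  expect_equal(m$avg_cosine_similarity, 1, tolerance = 1e-12)
  away <- trajectory(straight_walk(yaw = 180), meta0)
  win2 <- extract_analysis_window(away, env, 0.5)
  m2 <- compute_measures(win2, env, d, heading_2d = TRUE, vis_stride = 50)
  expect_equal(m2$avg_cosine_similarity, -1, tolerance = 1e-12)
})

test_that("a hand-built 5-sample window reproduces hand-computed measures", {
  env <- measure_env()
  d <- toy_dest(cx = 18, cy = 5, nx = -1, ny = 0, z0 = 0, z1 = 3, width = 4)
  s <- data.frame(t = c(0, 0.5, 1, 1.5, 2),
                  x = c(11.8, 12.2, 12.6, 13.0, 13.4),
                  y = c(5, 5.1, 5, 4.9, 5), z = 0,
                  yaw = c(0, 5, -5, 10, 0),
                  pitch = c(0, 2, -1, 3, 1))
  win <- trajectory(s, meta0)
  m <- compute_measures(win, env, d, fov = field_of_view(170, 170, 100),
                        n_rays = 100, vis_stride = 1)
  ## time: last minus first timestamp
  expect_equal(m$time_to_escalator, 2, tolerance = 1e-12)
  ## vertical head movement: mean absolute consecutive pitch difference
  expect_equal(m$avg_vertical_head_movement,
               mean(c(2, 3, 4, 2)), tolerance = 1e-12)
  ## cosine similarity: explicit 3D arithmetic per sample
  base <- c(13.5, 5, 0)
  cs <- vapply(1:5, function(i) {
    h <- c(cos(s$pitch[i] * pi / 180) * cos(s$yaw[i] * pi / 180),
           cos(s$pitch[i] * pi / 180) * sin(s$yaw[i] * pi / 180),
           sin(s$pitch[i] * pi / 180))
    v <- c(base[1] - s$x[i], base[2] - s$y[i], base[3] - (s$z[i] + 1.7))
    sum(h * v) / sqrt(sum(v^2))
  }, numeric(1))
  expect_equal(m$avg_cosine_similarity, mean(cs), tolerance = 1e-12)
  ## visibility: the 4 m door fills a wide unobstructed FOV at every sample
  expect_equal(m$avg_destination_visibility, 1, tolerance = 1e-12)
})

test_that("measures are stable under resampling a piecewise-linear path", {
  env <- measure_env()
  d <- toy_dest(cx = 20, cy = 5, nx = -1, ny = 0)
  ## speed chosen so the arrival-disc crossing (t = 10 s) lies on both
  ## sampling grids; the comparison then isolates the averaging behavior
  coarse <- trajectory(straight_walk(speed = 1.25, dt = 0.2, yaw = 3,
                                     pitch = 0), meta0)
  fine <- trajectory(straight_walk(speed = 1.25, dt = 0.05, yaw = 3,
                                   pitch = 0), meta0)
  mc <- compute_measures(extract_analysis_window(coarse, env, 0.5), env, d,
                         vis_stride = 10)
  mf <- compute_measures(extract_analysis_window(fine, env, 0.5), env, d,
                         vis_stride = 40)
  expect_equal(mc$time_to_escalator, mf$time_to_escalator, tolerance = 0.01)
  expect_equal(mc$avg_cosine_similarity, mf$avg_cosine_similarity,
               tolerance = 0.01)
  expect_equal(mc$avg_destination_visibility, mf$avg_destination_visibility,
               tolerance = 0.01)
})

test_that("visibility segmentation splits on exact zero", {
  df <- data.frame(avg_destination_visibility = c(0, 0.008, 0, 0.08))
  out <- segment_visibility_condition(df)
  expect_equal(as.character(out$condition), c("NV", "V", "NV", "V"))
  expect_equal(as.numeric(attr(out, "condition_counts")), c(2, 2))
  allz <- segment_visibility_condition(
    data.frame(avg_destination_visibility = c(0, 0)))
  expect_equal(sum(allz$condition == "V"), 0)
})

test_that("condition matching balances NV and V counts", {
  df <- data.frame(subject_id = rep(1:10, each = 3),
                   trial_id = 1:30, block = 1,
                   avg_destination_visibility = c(rep(0, 18), runif(12)))
  df <- segment_visibility_condition(df)
  out <- match_conditions(df, seed = 4)
  expect_equal(sum(out$condition == "NV"), sum(out$condition == "V"))
  expect_equal(nrow(out), 24)
})
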