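## Seeded synthetic-data generators. Two levels are provided: a fast
## measures-level generator (draws the per-trial behavioral measures directly
## from the linear model that defines the injected effects) and a
## trajectory-level generator that realizes the same effects geometrically as
## pose time series, so the full window-extraction / measurement / regression
## pipeline can be exercised end to end without any external data.

#' Synthetic study design
#'
#' Defaults reproduce the study structure: 69 participants, 8 destinations
#' per block repeated over 3 blocks (24 trials each, of which 12 target the
#' second floor and enter the analysis), two sessions, atria type varied
#' between participants. Injected effects default to the magnitudes the
#' human study reports; variance components are chosen to give realistic
#' trial-to-trial scatter.
#'
#' @param n_participants number of participants.
#' @param blocks number of blocks.
#' @param sessions number of sessions (participants split evenly).
#' @param effects named list of generative parameters: baselines
#'   (\code{time0}, \code{vhm0}, \code{cos0} for non-visible first-block
#'   trials), visibility-condition effects (\code{time_v}, \code{vhm_v},
#'   \code{cos_v}), block slopes (\code{time_block}, \code{vhm_block},
#'   \code{cos_block}), participant-intercept SDs (\code{sd_p_*}) and
#'   residual SDs (\code{sd_e_*}).
#' @param vis_range range of positive average destination visibility drawn
#'   for visible trials.
#' @param sample_dt trajectory sampling interval in seconds.
#' @param seed master seed.
#' @return list of class \code{wv_synth_design}.
#' @export
synthetic_design <- function(n_participants = 69, blocks = 3, sessions = 2,
                             effects = list(), vis_range = c(0.008, 0.080),
                             sample_dt = 0.1, seed = 1L) {
  eff <- list(time0 = 34.765, time_v = -4.935, time_block = -2.095,
              vhm0 = 0.041, vhm_v = -0.025, vhm_block = -0.002,
              cos0 = 0.723, cos_v = 0.107, cos_block = 0.039,
              sd_p_time = 4, sd_e_time = 5,
              sd_p_vhm = 0.012, sd_e_vhm = 0.02,
              sd_p_cos = 0.05, sd_e_cos = 0.10)
  eff[names(effects)] <- effects
  ## the deterministic part of cosine similarity must stay attainable
  cmax <- eff$cos0 + max(0, eff$cos_v) + max(0, eff$cos_block) * (blocks - 1)
  cmin <- eff$cos0 + min(0, eff$cos_v) + min(0, eff$cos_block) * (blocks - 1)
  if (cmax > 1 || cmin < -1)
    stop("injected cosine-similarity effects leave [-1, 1]")
  if (eff$time0 + min(0, eff$time_v) + min(0, eff$time_block) * (blocks - 1)
      <= 0)
    stop("injected time effects imply non-positive times")
  structure(list(n_participants = n_participants, blocks = blocks,
                 sessions = sessions, trials_per_block = 8L,
                 floor2_per_block = 4L, effects = eff,
                 vis_range = vis_range, sample_dt = sample_dt,
                 seed = as.integer(seed)),
            class = "wv_synth_design")
}

## participant-level frame: atria type alternates across ids; sessions split
## the sample in halves, so the two between-subject factors stay crossed
synth_participants <- function(design) {
  id <- seq_len(design$n_participants)
  data.frame(subject_id = sprintf("P%03d", id),
             atria_type = ifelse(id %% 2 == 1, "centralized", "distributed"),
             session = ifelse(id <= ceiling(design$n_participants / 2), 1,
                              design$sessions))
}

DEST_IDS <- c("F1_fwd_L", "F1_fwd_R", "F1_bwd_L", "F1_bwd_R",
              "F2_fwd_L", "F2_fwd_R", "F2_bwd_L", "F2_bwd_R")

#' Generate a measures-level synthetic trial table
#'
#' Draws the analyzed (second-floor) trials directly from the generating
#' linear model: measure = baseline + visibility effect + block slope +
#' participant intercept + residual. Forward-facing destinations are
#' visible (V) with a positive average destination visibility drawn from
#' \code{vis_range}; backwards-facing destinations are non-visible (NV,
#' visibility exactly 0).
#'
#' @param design a \code{wv_synth_design}.
#' @param seed optional seed override.
#' @return data frame shaped like \code{\link{measures_table}} output (with
#'   \code{condition} column), one row per analyzed trial.
#' @export
generate_synthetic_measures <- function(design = synthetic_design(),
                                        seed = design$seed) {
  set.seed(seed)
  pp <- synth_participants(design)
  e <- design$effects
  u_t <- stats::rnorm(nrow(pp), 0, e$sd_p_time)
  u_v <- stats::rnorm(nrow(pp), 0, e$sd_p_vhm)
  u_c <- stats::rnorm(nrow(pp), 0, e$sd_p_cos)
  f2 <- DEST_IDS[5:8]
  rows <- vector("list", nrow(pp) * design$blocks * 4L)
  k <- 0L
  for (i in seq_len(nrow(pp))) {
    for (b in seq_len(design$blocks)) {
      for (dst in f2) {
        k <- k + 1L
        fwd <- grepl("fwd", dst)
        x <- if (fwd) stats::runif(1, design$vis_range[1],
                                   design$vis_range[2]) else 0
        v <- as.numeric(x > 0)
        rows[[k]] <- data.frame(
          trial_id = sprintf("%s_b%d_%s", pp$subject_id[i], b, dst),
          subject_id = pp$subject_id[i], source = "synthetic",
          block = b, session = pp$session[i],
          atria_type = pp$atria_type[i], destination_id = dst,
          facing = if (fwd) "forward" else "backward",
          time_to_escalator = e$time0 + e$time_v * v +
            e$time_block * (b - 1) + u_t[i] +
            stats::rnorm(1, 0, e$sd_e_time),
          avg_vertical_head_movement = pmax(0, e$vhm0 + e$vhm_v * v +
            e$vhm_block * (b - 1) + u_v[i] +
            stats::rnorm(1, 0, e$sd_e_vhm)),
          avg_cosine_similarity = pmin(1, pmax(-1, e$cos0 + e$cos_v * v +
            e$cos_block * (b - 1) + u_c[i] +
            stats::rnorm(1, 0, e$sd_e_cos))),
          avg_destination_visibility = x,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$time_to_escalator <- pmax(3, out$time_to_escalator)
  segment_visibility_condition(out)
}

#' Generate synthetic pose trajectories
#'
#' Realizes the design as piecewise-linear pose time series: each trial
#' walks from the entrance towards its destination (second-floor trials via
#' the escalator base), with non-visible trials taking meandering detours
#' and slower progress so that the computed time-to-escalator carries the
#' injected visibility effect, yaw following the path direction with
#' condition-dependent jitter, and pitch following a random walk scaled to
#' the injected vertical-head-movement level. All 24 trials per participant
#' are produced (first-floor trials never reach the escalator and are
#' excluded from analysis by the measurement stage, as in the study design).
#'
#' @param design a \code{wv_synth_design}.
#' @param env a \code{wv_environment} (its entrance/escalator anchors the
#'   paths).
#' @param seed optional seed override.
#' @param floor2_only generate only the analyzed second-floor trials.
#' @return list of \code{wv_trajectory} with source "synthetic".
#' @export
generate_synthetic_trials <- function(design = synthetic_design(),
                                      env = build_building("centralized"),
                                      seed = design$seed,
                                      floor2_only = FALSE) {
  set.seed(seed)
  pp <- synth_participants(design)
  e <- design$effects
  dests <- if (floor2_only) DEST_IDS[5:8] else DEST_IDS
  n_trials <- nrow(pp) * design$blocks * length(dests)
  trial_seeds <- sample.int(2147483646L, n_trials)
  u_t <- stats::rnorm(nrow(pp), 0, e$sd_p_time)
  u_v <- stats::rnorm(nrow(pp), 0, e$sd_p_vhm)
  out <- vector("list", n_trials)
  k <- 0L
  for (i in seq_len(nrow(pp))) {
    ## per participant, atria type is fixed; trial order randomized per block
    envp <- if (pp$atria_type[i] == env$atria_type) env else
      build_building(pp$atria_type[i], env$params)
    for (b in seq_len(design$blocks)) {
      order_d <- sample(dests)
      for (dst in order_d) {
        k <- k + 1L
        fwd <- grepl("fwd", dst)
        f2 <- grepl("F2", dst)
        v <- as.numeric(f2 && fwd)
        target_t <- max(8, e$time0 + e$time_v * v +
                          e$time_block * (b - 1) + u_t[i] +
                          stats::rnorm(1, 0, e$sd_e_time))
        target_vhm <- max(0.002, e$vhm0 + e$vhm_v * v +
                            e$vhm_block * (b - 1) + u_v[i] +
                            stats::rnorm(1, 0, e$sd_e_vhm))
        out[[k]] <- synth_trial_path(
          envp, dst, f2, visible = fwd, target_t = target_t,
          target_vhm = target_vhm, dt = design$sample_dt,
          trial_seed = trial_seeds[k],
          meta = list(subject_id = pp$subject_id[i],
                      trial_id = sprintf("%s_b%d_%s", pp$subject_id[i], b,
                                         dst),
                      block = b, session = pp$session[i],
                      atria_type = pp$atria_type[i],
                      destination_id = dst, source = "synthetic"))
      }
    }
  }
  out
}

## Build one piecewise-linear trial path. For second-floor trials the window
## of interest ends at the escalator base; target_t controls the duration of
## that window via walking speed and meander length.
synth_trial_path <- function(env, dst, f2, visible, target_t, target_vhm,
                             dt, trial_seed, meta) {
  set.seed(trial_seed)
  start <- c(env$entrance$x, env$entrance$y)
  base <- env$escalator$base[1:2]
  d <- resolve_destination(env, dst)
  goal2 <- c(d$cx + 1.2 * d$nx, d$cy + 1.2 * d$ny)
  if (f2) {
    direct <- rbind(start,
                    c(mean(c(start[1], base[1])), stats::rnorm(1, 0, 0.6)),
                    base)
    if (visible) {
      wps <- direct
    } else {
      sgn <- sample(c(-1, 1), 1)
      amp <- 3.2
      wps <- rbind(start,
                   c(6, amp * sgn), c(12, -amp * sgn), c(17, amp * sgn),
                   c(21, stats::rnorm(1, 0, 0.8)),
                   base)
      ## the meander must stay walkable at <= 1.25 m/s within the target
      ## time; shrink its amplitude, or fall back to the direct path, when
      ## the drawn time is too short for the detour
      while (polyline_length(wps) > 1.25 * target_t && amp > 0.5) {
        amp <- amp * 0.6
        wps <- rbind(start,
                     c(6, amp * sgn), c(12, -amp * sgn), c(17, amp * sgn),
                     c(21, stats::rnorm(1, 0, 0.4)),
                     base)
      }
      if (polyline_length(wps) > 1.25 * target_t) wps <- direct
    }
    L <- polyline_length(wps)
    ## times shorter than the walk at top speed are physically unreachable;
    ## the realized duration then saturates at L / 1.25
    speed <- min(1.25, L / target_t)
  } else {
    wps <- rbind(start, goal2)
    L <- polyline_length(wps)
    speed <- min(1.25, max(0.6, L / max(target_t / 2, 4)))
  }
  dur <- L / speed
  tt <- seq(0, dur, by = dt)
  if (length(tt) < 2) tt <- c(0, dt)
  ss <- pmin(speed * tt, L)
  pos <- t(vapply(ss, function(s) polyline_point2(wps, s), numeric(2)))
  seg_dir <- atan2(c(diff(pos[, 2]), 0), c(diff(pos[, 1]), 1e-9))
  yaw_jit <- if (visible || !f2) 5 else 18
  yaw <- normalize_angle(rad2deg(seg_dir) + stats::rnorm(length(tt), 0,
                                                         yaw_jit))
  pw_sd <- target_vhm * sqrt(pi / 2)
  pitch <- cumsum(stats::rnorm(length(tt), 0, pw_sd))
  pitch <- pmax(-45, pmin(45, pitch))
  trajectory(data.frame(t = tt, x = pos[, 1], y = pos[, 2], z = 0,
                        yaw = yaw, pitch = pitch), meta)
}

polyline_point2 <- function(wps, s) {
  for (i in seq_len(nrow(wps) - 1)) {
    seg <- sqrt(sum((wps[i + 1, ] - wps[i, ])^2))
    if (s <= seg + 1e-12)
      return(wps[i, ] + (wps[i + 1, ] - wps[i, ]) * s / max(seg, 1e-12))
    s <- s - seg
  }
  wps[nrow(wps), ]
}

#' Generate a synthetic human-like benchmark measures table
#'
#' Stand-in for a human benchmark when the deposited dataset is not at hand,
#' labelled source "human". At the \code{"trajectory"} level (recommended
#' for agent comparisons) the benchmark runs the full pipeline — synthetic
#' pose trajectories scored by \code{\link{measures_table}} — so its measure
#' scales are commensurable with agent trials scored the same way. The
#' \code{"measures"} level draws the per-trial table directly from the
#' generating linear model and is faster, suited to regression-side tests.
#'
#' @param design a \code{wv_synth_design}.
#' @param seed seed.
#' @param env environment for the trajectory-level pipeline.
#' @param level "trajectory" or "measures".
#' @param vis_stride visibility sampling stride for the trajectory level.
#' @return measures data frame with source "human".
#' @export
synthetic_human_benchmark <- function(design = synthetic_design(),
                                      seed = design$seed,
                                      env = build_building("centralized"),
                                      level = c("trajectory", "measures"),
                                      vis_stride = 8) {
  level <- match.arg(level)
  if (level == "measures") {
    m <- generate_synthetic_measures(design, seed)
  } else {
    trs <- generate_synthetic_trials(design, env, seed, floor2_only = TRUE)
    m <- measures_table(trs, env, vis_stride = vis_stride)
    m <- segment_visibility_condition(m)
  }
  m$source <- "human"
  m
}
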