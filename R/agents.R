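## The visibility-based cognitive agent and the shortest-path baseline.
## The cognitive agent is a finite-state machine: from the spawn state it
## moves straight for the escalator when the destination is in sight and
## otherwise explores, steering towards the minimum-drift cell visible in its
## field of view while a short-term memory of visited zones prevents loops.
## Reaching the escalator it switches floors; on the upper floor it routes to
## the destination once seen. The baseline agent routes the entire way with
## A* and ignores visibility.

#' Agent parameters
#'
#' Body and camera geometry match the avatar used for the human trials:
#' height 1.8 m, eye height 1.7 m, shoulder width 0.25 m, maximum forward
#' speed 1.3 m/s, backwards/lateral speed 0.6 m/s. The perception cone is
#' 150 degrees horizontal with a 100 m range; rotational dynamics (turn
#' rate) and the integration step are model parameters.
#'
#' @param height,eye_height,shoulder_width body geometry in meters.
#' @param forward_speed,lateral_backward_speed speeds in m/s.
#' @param fov a \code{wv_fov} for perception.
#' @param turn_rate yaw rate in degrees per second.
#' @param dt internal integration step in seconds.
#' @param log_dt pose logging interval in seconds.
#' @param n_sight_rays rays for the destination-in-sight test.
#' @return list of class \code{wv_agent_params}.
#' @export
agent_params <- function(height = 1.8, eye_height = 1.7,
                         shoulder_width = 0.25, forward_speed = 1.3,
                         lateral_backward_speed = 0.6, fov = agent_fov(),
                         turn_rate = 90, dt = 0.1, log_dt = 0.2,
                         n_sight_rays = 25) {
  stopifnot(forward_speed > 0, lateral_backward_speed > 0, turn_rate > 0,
            dt > 0, log_dt >= dt)
  structure(list(height = height, eye_height = eye_height,
                 shoulder_width = shoulder_width,
                 forward_speed = forward_speed,
                 lateral_backward_speed = lateral_backward_speed,
                 fov = fov, turn_rate = turn_rate, dt = dt, log_dt = log_dt,
                 n_sight_rays = n_sight_rays),
            class = "wv_agent_params")
}

#' Initialize an agent state
#'
#' @param env a \code{wv_environment}.
#' @param zones a \code{wv_zones} table for the environment.
#' @param initial_heading spawn yaw in degrees.
#' @return list of class \code{wv_agent_state} (mode, pose, floor, visited
#'   zones, current plan, clock).
#' @export
agent_init <- function(env, zones, initial_heading = 0) {
  structure(list(mode = "INITIAL",
                 pose = list(x = env$entrance$x, y = env$entrance$y,
                             z = env$entrance$z,
                             yaw = normalize_angle(initial_heading),
                             pitch = 0),
                 floor = 1L,
                 visited_zones = integer(0),
                 waypoints = NULL, wp_i = 0L,
                 target_cell = NA_integer_,
                 on_ramp = FALSE, ramp_s = 0,
                 zones = zones,
                 explore_targets = integer(0),
                 time = 0, done = FALSE, failed = FALSE,
                 failure = NA_character_),
            class = "wv_agent_state")
}

#' Perceive the environment from the current agent state
#'
#' @param state a \code{wv_agent_state}.
#' @param env a \code{wv_environment}.
#' @param grid a \code{wv_navgrid}.
#' @param field a \code{wv_drift_field}.
#' @param dest destination id or row.
#' @param params a \code{wv_agent_params}.
#' @return list with \code{destination_in_sight} (logical),
#'   \code{visible_cells} (global indices) and \code{drift} (their drift
#'   values).
#' @export
perceive <- function(state, env, grid, field, dest,
                     params = agent_params()) {
  vis <- destination_visibility(state$pose, dest, env, params$fov,
                                n_rays = params$n_sight_rays,
                                eye_height = params$eye_height)
  cells <- cells_in_fov(grid, env, state$floor, state$pose, params$fov,
                        eye_height = params$eye_height)
  list(destination_in_sight = vis$n_rays_reaching >= 1,
       visible_cells = cells,
       drift = field$drift[cells])
}

## waypoints from a same-floor cell path, collinear runs compressed
path_waypoints <- function(grid, path) {
  m <- cbind(grid$cell_x[path], grid$cell_y[path])
  if (nrow(m) <= 2) return(m)
  keep <- c(TRUE, rep(FALSE, nrow(m) - 2), TRUE)
  d <- diff(m)
  for (i in 2:(nrow(m) - 1))
    if (abs(d[i - 1, 1] * d[i, 2] - d[i - 1, 2] * d[i, 1]) > 1e-9)
      keep[i] <- TRUE
  m[keep, , drop = FALSE]
}

set_plan <- function(state, grid, goal_cell) {
  from <- nearest_cell(grid, state$floor, state$pose$x, state$pose$y)
  res <- plan_shortest_path(grid, from, goal_cell)
  ## same-floor plans only; inter-floor movement goes through the ramp mode
  state$waypoints <- path_waypoints(grid, res$path)
  state$wp_i <- 1L
  state
}

## advance the pose one dt along the current waypoint plan; returns state
advance_along_plan <- function(state, params) {
  p <- state$pose
  dt <- params$dt
  if (is.null(state$waypoints) || state$wp_i > nrow(state$waypoints)) {
    state$time <- state$time + dt
    return(state)
  }
  wp <- state$waypoints[state$wp_i, ]
  dx <- wp[1] - p$x; dy <- wp[2] - p$y
  d <- sqrt(dx^2 + dy^2)
  if (d < 1e-6) {
    state$wp_i <- state$wp_i + 1L
    state$time <- state$time + dt
    return(state)
  }
  des <- rad2deg(atan2(dy, dx))
  err <- normalize_angle(des - p$yaw)
  dyaw <- sign(err) * min(abs(err), params$turn_rate * dt)
  p$yaw <- normalize_angle(p$yaw + dyaw)
  err <- normalize_angle(des - p$yaw)
  if (abs(err) <= 90) {
    ## walk towards the waypoint; stop there if reached within this step
    step <- min(params$forward_speed * dt, d)
    p$x <- p$x + step * dx / d
    p$y <- p$y + step * dy / d
    if (step >= d - 1e-9) state$wp_i <- state$wp_i + 1L
  }
  state$pose <- p
  state$time <- state$time + dt
  state
}

plan_finished <- function(state) {
  is.null(state$waypoints) || state$wp_i > nrow(state$waypoints)
}

## pick the minimum-drift visible cell outside visited zones; ties break to
## the nearest cell, then the lowest index (determinism)
explore_candidate <- function(state, percept, grid) {
  cells <- percept$visible_cells
  if (!length(cells)) return(NA_integer_)
  zid <- zone_of(state$zones, state$floor, grid$cell_x[cells],
                 grid$cell_y[cells])
  here <- zone_of(state$zones, state$floor, state$pose$x, state$pose$y)
  ok <- !is.na(zid) & !(zid %in% c(state$visited_zones, here))
  cells <- cells[ok]
  if (!length(cells)) return(NA_integer_)
  dr <- percept$drift[ok]
  dd <- dist2d(grid$cell_x[cells], grid$cell_y[cells],
               state$pose$x, state$pose$y)
  cells[order(dr, dd, cells)[1]]
}

## nearest cell of the nearest unvisited zone on this floor (used when the
## field of view currently shows no admissible cell but unvisited zones
## remain: the agent reorients towards them instead of giving up)
fallback_candidate <- function(state, grid) {
  zf <- state$zones[state$zones$floor == state$floor, ]
  here <- zone_of(state$zones, state$floor, state$pose$x, state$pose$y)
  zf <- zf[!(zf$id %in% c(state$visited_zones, here)), ]
  if (!nrow(zf)) return(NA_integer_)
  zx <- (zf$x0 + zf$x1) / 2; zy <- (zf$y0 + zf$y1) / 2
  k <- which.min(dist2d(zx, zy, state$pose$x, state$pose$y))
  nearest_cell(grid, state$floor, zx[k], zy[k])
}

mark_zone <- function(state) {
  z <- zone_of(state$zones, state$floor, state$pose$x, state$pose$y)
  if (!is.na(z) && !(z %in% state$visited_zones))
    state$visited_zones <- c(state$visited_zones, z)
  state
}

#' Advance the cognitive agent one time step
#'
#' Implements the finite-state machine transitions: INITIAL dispatches to
#' MOVE_TO_ESCALATOR (destination in sight) or EXPLORE; EXPLORE steers to
#' the minimum-drift visible cell outside visited zones and transitions on
#' sight of the destination or exhaustion of zones; MOVE_TO_ESCALATOR
#' follows A* to the base and rides the ramp; at the top, the agent routes
#' to the destination if it is visible and otherwise explores the upper
#' floor. Per-step displacement never exceeds forward_speed * dt.
#'
#' @param state a \code{wv_agent_state}.
#' @param percept output of \code{\link{perceive}} for this state (may be
#'   NULL in the movement states, which do not consult perception).
#' @param env,grid,field,dest,params as in \code{\link{perceive}}.
#' @return the updated \code{wv_agent_state}.
#' @export
agent_step <- function(state, percept, env, grid, field, dest,
                       params = agent_params()) {
  d <- resolve_destination(env, dest)
  if (state$mode == "INITIAL") {
    state <- mark_zone(state)
    state$mode <- if (percept$destination_in_sight) "MOVE_TO_ESCALATOR"
                  else "EXPLORE"
    if (state$mode == "MOVE_TO_ESCALATOR")
      state <- set_plan(state, grid, grid$base_cell)
    return(state)                      # transition consumes no time
  }

  if (state$mode == "EXPLORE") {
    state <- mark_zone(state)
    if (percept$destination_in_sight) {
      if (state$floor == 1L) {
        state$mode <- "MOVE_TO_ESCALATOR"
        state <- set_plan(state, grid, grid$base_cell)
      } else {
        state$mode <- "MOVE_TO_DESTINATION"
        state <- set_plan(state, grid, destination_cell(grid, env, d))
      }
      return(state)
    }
    if (is.na(state$target_cell) || plan_finished(state)) {
      cand <- explore_candidate(state, percept, grid)
      if (is.na(cand)) cand <- fallback_candidate(state, grid)
      if (is.na(cand)) {
        if (state$floor == 1L) {
          state$mode <- "MOVE_TO_ESCALATOR"
          state <- set_plan(state, grid, grid$base_cell)
        } else {
          state$failed <- TRUE
          state$failure <- "upper floor exhausted without sighting the goal"
          state$mode <- "FAILED"
        }
        return(state)
      }
      state$target_cell <- cand
      state$explore_targets <- c(state$explore_targets,
                                 zone_of(state$zones, state$floor,
                                         grid$cell_x[cand],
                                         grid$cell_y[cand]))
      state <- set_plan(state, grid, cand)
    }
    state <- advance_along_plan(state, params)
    if (plan_finished(state)) state$target_cell <- NA_integer_
    return(mark_zone(state))
  }

  if (state$mode == "MOVE_TO_ESCALATOR") {
    if (state$on_ramp) return(ramp_step(state, env, grid, d, params))
    if (plan_finished(state)) {
      state$on_ramp <- TRUE
      state$ramp_s <- 0
      return(ramp_step(state, env, grid, d, params))
    }
    return(advance_along_plan(state, params))
  }

  if (state$mode == "MOVE_TO_DESTINATION") {
    if (plan_finished(state)) {
      state$mode <- "DONE"
      state$done <- TRUE
      return(state)
    }
    return(advance_along_plan(state, params))
  }
  state
}

## One dt of escalator motion: walk up to the bottom step if not there yet,
## then ride the polyline at forward speed. Returns the state plus a
## `finished` flag; displacement per dt stays within the speed cap.
ramp_motion <- function(state, env, params) {
  pl <- env$escalator$polyline
  total <- polyline_length(pl)
  step <- params$forward_speed * params$dt
  if (state$ramp_s <= 1e-12) {
    dx <- pl[1, 1] - state$pose$x; dy <- pl[1, 2] - state$pose$y
    dd <- sqrt(dx^2 + dy^2)
    if (dd > step) {                    # still approaching the bottom step
      state$pose$x <- state$pose$x + step * dx / dd
      state$pose$y <- state$pose$y + step * dy / dd
      state$pose$yaw <- rad2deg(atan2(dy, dx))
      state$time <- state$time + params$dt
      return(list(state = state, finished = FALSE))
    }
    state$ramp_s <- step - dd           # leftover motion starts the ride
  } else {
    state$ramp_s <- state$ramp_s + step
  }
  state$ramp_s <- min(total, state$ramp_s)
  q <- point_on_polyline(pl, state$ramp_s)
  dirp <- point_on_polyline(pl, min(total, state$ramp_s + 0.2))
  if (any(abs(dirp[1:2] - q[1:2]) > 1e-9))
    state$pose$yaw <- rad2deg(atan2(dirp[2] - q[2], dirp[1] - q[1]))
  state$pose$x <- q[1]; state$pose$y <- q[2]; state$pose$z <- q[3]
  state$time <- state$time + params$dt
  list(state = state, finished = state$ramp_s >= total - 1e-9)
}

## ride the escalator ramp; on arrival at the top re-evaluate sight
ramp_step <- function(state, env, grid, d, params) {
  rm <- ramp_motion(state, env, params)
  state <- rm$state
  if (rm$finished) {
    state$on_ramp <- FALSE
    state$floor <- 2L
    state$pose$z <- env$floors[[2]]$elevation
    state$waypoints <- NULL
    ## FSM branch at the top: route to the destination if it is in sight,
    ## otherwise keep exploring on the upper floor
    vis <- destination_visibility(state$pose, d, env, params$fov,
                                  n_rays = params$n_sight_rays,
                                  eye_height = params$eye_height)
    if (vis$n_rays_reaching >= 1) {
      state$mode <- "MOVE_TO_DESTINATION"
      state <- set_plan(state, grid, destination_cell(grid, env, d))
    } else {
      state$mode <- "EXPLORE"
      state$target_cell <- NA_integer_
    }
  }
  state
}

point_on_polyline <- function(pl, s) {
  for (i in seq_len(nrow(pl) - 1)) {
    seg <- sqrt(sum((pl[i + 1, ] - pl[i, ])^2))
    if (s <= seg + 1e-12) return(pl[i, ] + (pl[i + 1, ] - pl[i, ]) * s / seg)
    s <- s - seg
  }
  pl[nrow(pl), ]
}

## walkable cell in front of a destination door
destination_cell <- function(grid, env, d) {
  nearest_cell(grid, d$floor, d$cx + 0.8 * d$nx, d$cy + 0.8 * d$ny)
}

#' Run one agent trial
#'
#' Simulates a single wayfinding trial from the entrance to the given
#' destination and returns the pose log as a trajectory (sampled every
#' \code{params$log_dt} seconds).
#'
#' The cognitive agent iterates perceive/step until DONE, failure, or the
#' time cap. The shortest-path agent plans a single A* route from the
#' entrance to the destination (through the escalator link) and follows it
#' with the same kinematics, ignoring visibility throughout.
#'
#' @param agent_type "cognitive" or "shortest_path".
#' @param env a \code{wv_environment}.
#' @param grid a \code{wv_navgrid}.
#' @param field a \code{wv_drift_field} (unused by the baseline).
#' @param dest destination id or row.
#' @param initial_heading spawn yaw in degrees.
#' @param seed RNG seed recorded with the trial (trials are deterministic
#'   given heading; the seed namespaces any auxiliary randomness).
#' @param params a \code{wv_agent_params}.
#' @param zones precomputed \code{wv_zones} (built on the fly if NULL).
#' @param max_time simulation time cap in seconds.
#' @param agent_id subject identifier stored in the trajectory metadata.
#' @return a \code{wv_trajectory} with attributes \code{completed},
#'   \code{failure}, \code{explore_targets} (zone ids chosen as exploration
#'   targets) and \code{modes} (per-log-sample FSM mode).
#' @export
run_trial <- function(agent_type = c("cognitive", "shortest_path"),
                      env, grid, field, dest, initial_heading = 0,
                      seed = 1L, params = agent_params(), zones = NULL,
                      max_time = 600, agent_id = "agent_1") {
  agent_type <- match.arg(agent_type)
  d <- resolve_destination(env, dest)
  if (is.null(zones)) zones <- decompose_zones(env)
  state <- agent_init(env, zones, initial_heading)
  set.seed(as.integer(seed %% .Machine$integer.max))

  log_every <- max(1L, round(params$log_dt / params$dt))
  log <- list(as.numeric(c(0, state$pose$x, state$pose$y, state$pose$z,
                           state$pose$yaw, state$pose$pitch)))
  modes <- state$mode

  if (agent_type == "shortest_path") {
    from <- nearest_cell(grid, 1L, state$pose$x, state$pose$y)
    res <- plan_shortest_path(grid, from, destination_cell(grid, env, d))
    split <- which(diff(grid$cell_floor[res$path]) != 0)
    if (length(split)) {
      state$mode <- "MOVE_TO_ESCALATOR"
      state$waypoints <- path_waypoints(grid, res$path[seq_len(split)])
      post <- res$path[(split + 1):length(res$path)]
    } else {
      state$mode <- "MOVE_TO_DESTINATION"
      state$waypoints <- path_waypoints(grid, res$path)
      post <- integer(0)
    }
    state$wp_i <- 1L
    step_i <- 0L
    while (!state$done && state$time < max_time) {
      if (state$mode == "MOVE_TO_ESCALATOR") {
        if (state$on_ramp || plan_finished(state)) {
          if (!state$on_ramp) { state$on_ramp <- TRUE; state$ramp_s <- 0 }
          rm <- ramp_motion(state, env, params)
          state <- rm$state
          if (rm$finished) {
            state$on_ramp <- FALSE
            state$floor <- 2L
            state$pose$z <- env$floors[[2]]$elevation
            state$mode <- "MOVE_TO_DESTINATION"
            state$waypoints <- path_waypoints(grid, post)
            state$wp_i <- 1L
          }
        } else state <- advance_along_plan(state, params)
      } else {
        if (plan_finished(state)) { state$done <- TRUE }
        else state <- advance_along_plan(state, params)
      }
      step_i <- step_i + 1L
      if ((step_i %% log_every == 0L || state$done) &&
          state$time > log[[length(log)]][1] + 1e-9) {
        log[[length(log) + 1]] <- as.numeric(c(state$time, state$pose$x,
                                               state$pose$y, state$pose$z,
                                               state$pose$yaw,
                                               state$pose$pitch))
        modes <- c(modes, state$mode)
      }
    }
  } else {
    step_i <- 0L
    while (!state$done && !state$failed && state$time < max_time) {
      percept <- if (state$mode %in% c("INITIAL", "EXPLORE"))
        perceive(state, env, grid, field, d, params) else NULL
      t_before <- state$time
      state <- agent_step(state, percept, env, grid, field, d, params)
      if (state$time <= t_before) next   # instantaneous FSM transition
      step_i <- step_i + 1L
      if ((step_i %% log_every == 0L || state$done || state$failed) &&
          state$time > log[[length(log)]][1] + 1e-9) {
        log[[length(log) + 1]] <- as.numeric(c(state$time, state$pose$x,
                                               state$pose$y, state$pose$z,
                                               state$pose$yaw,
                                               state$pose$pitch))
        modes <- c(modes, state$mode)
      }
    }
  }
  if (!state$done && !state$failed) {
    state$failed <- TRUE
    state$failure <- "time cap exceeded"
  }
  m <- do.call(rbind, log)
  samples <- data.frame(t = m[, 1], x = m[, 2], y = m[, 3], z = m[, 4],
                        yaw = m[, 5], pitch = m[, 6])
  tr <- trajectory(samples,
                   list(subject_id = agent_id,
                        trial_id = sprintf("%s_%s_%s", agent_id, d$id, seed),
                        block = 1, session = 1,
                        atria_type = env$atria_type,
                        destination_id = d$id,
                        source = if (agent_type == "cognitive")
                          "cognitive_agent" else "shortest_path_agent"))
  attr(tr, "completed") <- state$done
  attr(tr, "failure") <- state$failure
  attr(tr, "explore_targets") <- state$explore_targets
  attr(tr, "modes") <- modes
  tr
}
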