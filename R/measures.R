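## Behavioral trajectory measures. All four per-trial scalars are computed
## over the analysis window: the trajectory prefix from trial start until the
## first arrival at the bottom step of the escalator.

#' Extract the analysis window of a trial
#'
#' Returns the prefix of the trajectory ending at the first sample whose
#' horizontal distance to the escalator base is at most
#' \code{arrival_radius}. Trials that never reach the escalator are flagged
#' incomplete via an error of class \code{wv_incomplete_trial} and are
#' excluded from measures by the table builder.
#'
#' @param traj a \code{wv_trajectory}.
#' @param env a \code{wv_environment}.
#' @param arrival_radius arrival radius in meters around the bottom step.
#' @return a \code{wv_trajectory} holding the window.
#' @export
extract_analysis_window <- function(traj, env, arrival_radius = 0.5) {
  s <- traj$samples
  base <- env$escalator$base
  d0 <- dist2d(s$x[1], s$y[1], env$entrance$x, env$entrance$y)
  if (d0 > max(arrival_radius, 1))
    warning("trajectory does not start at the entrance")
  d <- dist2d(s$x, s$y, base[1], base[2])
  hit <- which(d <= arrival_radius & abs(s$z - base[3]) < 1.5)
  if (!length(hit)) {
    cond <- structure(class = c("wv_incomplete_trial", "error", "condition"),
                      list(message = "trial never reached the escalator base",
                           call = NULL))
    stop(cond)
  }
  end <- hit[1]
  if (end < 2) end <- 2
  trajectory(s[seq_len(end), ], traj$meta)
}

## 3D unit heading vector from yaw/pitch in degrees
heading_vector <- function(yaw, pitch) {
  cy <- cos(deg2rad(yaw)); sy <- sin(deg2rad(yaw))
  cp <- cos(deg2rad(pitch)); sp <- sin(deg2rad(pitch))
  cbind(cp * cy, cp * sy, sp)
}

#' Compute the four behavioral measures over an analysis window
#'
#' \itemize{
#'   \item \code{time_to_escalator}: window duration in seconds.
#'   \item \code{avg_vertical_head_movement}: mean absolute difference in
#'     camera elevation angle (pitch, degrees) between consecutive samples.
#'   \item \code{avg_cosine_similarity}: mean cosine of the angle between the
#'     3D heading vector and the vector from the eye point to the escalator's
#'     bottom step (1 = heading straight at it, -1 = directly away). Set
#'     \code{heading_2d = TRUE} to project both vectors to the horizontal
#'     plane.
#'   \item \code{avg_destination_visibility}: mean ray-cast destination
#'     visibility fraction over the window's samples; \code{vis_stride}
#'     subsamples dense logs (every n-th sample) for speed.
#' }
#'
#' @param window a \code{wv_trajectory} from
#'   \code{\link{extract_analysis_window}}.
#' @param env a \code{wv_environment}.
#' @param dest destination id or row; defaults to the window's metadata.
#' @param fov observer field of view for the visibility rays.
#' @param n_rays rays per visibility sample.
#' @param vis_stride sample stride for the visibility average.
#' @param heading_2d project heading and target vectors to the plan.
#' @param eye_height eye height above the logged z.
#' @return list of class \code{wv_measures} with the four scalars.
#' @export
compute_measures <- function(window, env, dest = NULL, fov = observer_fov(),
                             n_rays = 100, vis_stride = 1,
                             heading_2d = FALSE,
                             eye_height = env$params$eye_height) {
  s <- window$samples
  if (nrow(s) < 2) stop("analysis window shorter than 2 samples")
  if (is.null(dest)) dest <- window$meta$destination_id
  d <- resolve_destination(env, dest)
  base <- env$escalator$base

  tte <- s$t[nrow(s)] - s$t[1]
  avhm <- mean(abs(diff(s$pitch)))

  h <- heading_vector(s$yaw, s$pitch)
  vx <- base[1] - s$x
  vy <- base[2] - s$y
  vz <- base[3] - (s$z + eye_height)
  if (heading_2d) {
    h[, 3] <- 0
    h <- h / pmax(sqrt(rowSums(h^2)), 1e-12)
    vz <- rep(0, length(vz))
  }
  vn <- pmax(sqrt(vx^2 + vy^2 + vz^2), 1e-12)
  cossim <- (h[, 1] * vx + h[, 2] * vy + h[, 3] * vz) / vn
  acs <- mean(cossim)

  idx <- unique(c(seq(1, nrow(s), by = max(1L, as.integer(vis_stride))),
                  nrow(s)))
  vis <- vapply(idx, function(i) {
    destination_visibility(list(x = s$x[i], y = s$y[i], z = s$z[i],
                                yaw = s$yaw[i], pitch = s$pitch[i]),
                           d, env, fov, n_rays,
                           eye_height = eye_height)$fraction_visible
  }, numeric(1))
  structure(list(time_to_escalator = tte,
                 avg_vertical_head_movement = avhm,
                 avg_cosine_similarity = acs,
                 avg_destination_visibility = mean(vis)),
            class = "wv_measures")
}

#' Build a per-trial measures table
#'
#' Applies window extraction and measure computation to a list of
#' trajectories, keeping trial metadata and flagging incomplete trials
#' (excluded from the measures but counted).
#'
#' @param trajs list of \code{wv_trajectory}.
#' @param env a \code{wv_environment}.
#' @inheritParams compute_measures
#' @param arrival_radius arrival radius for the analysis window.
#' @return data frame, one row per completed trial, with metadata columns,
#'   the four measures, and the facing of the destination; the number of
#'   incomplete trials is attached as attribute \code{n_incomplete}.
#' @export
measures_table <- function(trajs, env, fov = observer_fov(),
                           arrival_radius = 0.5, n_rays = 100,
                           vis_stride = 1, heading_2d = FALSE) {
  rows <- list()
  incomplete <- 0L
  for (tr in trajs) {
    win <- tryCatch(extract_analysis_window(tr, env, arrival_radius),
                    wv_incomplete_trial = function(e) NULL)
    if (is.null(win)) { incomplete <- incomplete + 1L; next }
    m <- compute_measures(win, env, fov = fov, n_rays = n_rays,
                          vis_stride = vis_stride, heading_2d = heading_2d)
    d <- resolve_destination(env, tr$meta$destination_id)
    rows[[length(rows) + 1]] <- data.frame(
      trial_id = tr$meta$trial_id, subject_id = tr$meta$subject_id,
      source = tr$meta$source, block = tr$meta$block,
      session = tr$meta$session, atria_type = tr$meta$atria_type,
      destination_id = tr$meta$destination_id, facing = d$facing,
      time_to_escalator = m$time_to_escalator,
      avg_vertical_head_movement = m$avg_vertical_head_movement,
      avg_cosine_similarity = m$avg_cosine_similarity,
      avg_destination_visibility = m$avg_destination_visibility,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_incomplete") <- incomplete
  out
}

#' Segment trials into visibility conditions
#'
#' NV ("non-visible") trials have an average destination visibility exactly
#' equal to zero over the analysis window; V trials have a positive value.
#'
#' @param measures a measures data frame (needs column
#'   \code{avg_destination_visibility}).
#' @return the data frame with a \code{condition} factor (levels NV, V);
#'   per-condition counts are attached as attribute \code{condition_counts}.
#' @export
segment_visibility_condition <- function(measures) {
  cond <- ifelse(measures$avg_destination_visibility > 0, "V", "NV")
  measures$condition <- factor(cond, levels = c("NV", "V"))
  attr(measures, "condition_counts") <- table(measures$condition)
  measures
}

#' Match visibility conditions by random subsampling
#'
#' Optional balancing step: subsamples the larger condition uniformly at
#' random (stratified by participant and block where possible) so both
#' conditions contain the same number of trials. How the original study
#' matched its conditions is not documented, so this matcher is provided as
#' one reasonable choice, not as canonical; the default analysis path uses
#' all trials.
#'
#' @param measures a segmented measures data frame.
#' @param seed RNG seed.
#' @return a subsampled data frame with equal NV and V counts.
#' @export
match_conditions <- function(measures, seed = 1) {
  stopifnot("condition" %in% names(measures))
  n <- table(measures$condition)
  small <- names(n)[which.min(n)]
  big <- setdiff(c("NV", "V"), small)
  keep_small <- measures[measures$condition == small, ]
  pool <- measures[measures$condition == big, ]
  set.seed(seed)
  take <- sample(nrow(pool), nrow(keep_small))
  out <- rbind(keep_small, pool[take, ])
  out[order(out$subject_id, out$trial_id), ]
}
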