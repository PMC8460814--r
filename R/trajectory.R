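## Trajectory container and CSV I/O. A trajectory is a timestamped pose
## series (position, yaw, pitch) plus trial metadata. The on-disk dialect is
## a single long CSV holding any number of trials.

TRAJ_COLS <- c("trial_id", "subject_id", "source", "block", "session",
               "atria_type", "destination_id", "t", "x", "y", "z",
               "yaw", "pitch")

#' Construct a trajectory
#'
#' @param samples data frame with columns t, x, y, z, yaw, pitch; t strictly
#'   increasing, at least 2 rows.
#' @param meta named list: subject_id, trial_id, block, session, atria_type,
#'   destination_id, source (one of "human", "cognitive_agent",
#'   "shortest_path_agent", "synthetic").
#' @return object of class \code{wv_trajectory}.
#' @export
trajectory <- function(samples, meta) {
  stopifnot(is.data.frame(samples),
            all(c("t", "x", "y", "z", "yaw", "pitch") %in% names(samples)))
  if (nrow(samples) < 2) stop("a trajectory needs at least 2 samples")
  if (any(diff(samples$t) <= 0)) stop("timestamps must be strictly increasing")
  need <- c("subject_id", "trial_id", "block", "session", "atria_type",
            "destination_id", "source")
  missing <- setdiff(need, names(meta))
  if (length(missing)) stop("missing metadata: ", paste(missing, collapse = ", "))
  structure(list(samples = samples[, c("t", "x", "y", "z", "yaw", "pitch")],
                 meta = meta[need]),
            class = "wv_trajectory")
}

#' @export
print.wv_trajectory <- function(x, ...) {
  cat(sprintf("<wv_trajectory %s/%s: %d samples, %.1f s, source=%s>\n",
              x$meta$subject_id, x$meta$trial_id, nrow(x$samples),
              diff(range(x$samples$t)), x$meta$source))
  invisible(x)
}

#' Write trajectories to CSV (native dialect)
#'
#' @param trajs a list of \code{wv_trajectory} objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "wv_trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    cbind(data.frame(trial_id = tr$meta$trial_id,
                     subject_id = tr$meta$subject_id,
                     source = tr$meta$source,
                     block = tr$meta$block,
                     session = tr$meta$session,
                     atria_type = tr$meta$atria_type,
                     destination_id = tr$meta$destination_id),
          tr$samples)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' The \code{native} dialect matches \code{\link{write_trajectories}}. The
#' \code{unity} dialect accepts logs in game-engine convention (y-up,
#' left-handed) and converts them at this boundary: positions
#' \code{(x, y, z)} map to \code{(x, z, y)} (the engine's y is elevation) and
#' yaw/pitch flip sign (left-handed yaw; pitch positive-down becomes
#' positive-up).
#'
#' @param path input CSV.
#' @param dialect "native" or "unity".
#' @return list of \code{wv_trajectory} objects.
#' @export
read_trajectories <- function(path, dialect = c("native", "unity")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRAJ_COLS, names(df))
  if (length(missing))
    stop("trajectory file missing column(s): ", paste(missing, collapse = ", "))
  if (dialect == "unity") {
    tmp <- df$y
    df$y <- df$z
    df$z <- tmp
    df$yaw <- normalize_angle(-df$yaw)
    df$pitch <- -df$pitch
  }
  out <- list()
  for (tid in unique(df$trial_id)) {
    rows <- df[df$trial_id == tid, ]
    rows <- rows[order(rows$t), ]
    if (any(diff(rows$t) <= 0))
      stop(sprintf("non-monotone timestamps within trial '%s'", tid))
    out[[length(out) + 1]] <- trajectory(
      rows[, c("t", "x", "y", "z", "yaw", "pitch")],
      list(subject_id = rows$subject_id[1], trial_id = tid,
           block = rows$block[1], session = rows$session[1],
           atria_type = rows$atria_type[1],
           destination_id = rows$destination_id[1],
           source = rows$source[1]))
  }
  out
}
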