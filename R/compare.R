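## Monte-Carlo simulation experiments and the agent-versus-human comparison:
## L1 differences against per-destination human benchmarks, a mixed-model on
## those differences, spatial kernel-density rasters of paths, and dynamic
## time warping between individual trajectories.

#' Monte-Carlo experiment configuration
#'
#' Each sample is one simulated trial whose random variable is the agent's
#' initial heading, drawn uniformly on the circle. Destinations cycle
#' through the given set.
#'
#' @param n_samples number of trials (the full-scale experiment uses 1600).
#' @param agent_type "cognitive" or "shortest_path".
#' @param destinations destination ids; defaults to all second-floor doors.
#' @param master_seed seed from which all per-sample randomness derives.
#' @return list of class \code{wv_mc_config}.
#' @export
monte_carlo_config <- function(n_samples = 1600,
                               agent_type = c("cognitive", "shortest_path"),
                               destinations = NULL, master_seed = 1L) {
  agent_type <- match.arg(agent_type)
  stopifnot(n_samples >= 1)
  structure(list(n_samples = as.integer(n_samples), agent_type = agent_type,
                 destinations = destinations,
                 master_seed = as.integer(master_seed)),
            class = "wv_mc_config")
}

#' Run a Monte-Carlo simulation experiment
#'
#' @param cfg a \code{wv_mc_config}.
#' @param env,grid,field environment, navigation grid and drift field.
#' @param params agent parameters.
#' @param zones precomputed zones (built once if NULL).
#' @param max_time per-trial time cap in seconds.
#' @return list of \code{wv_trajectory}; failed trials carry
#'   \code{attr(, "completed") == FALSE}.
#' @export
run_monte_carlo <- function(cfg, env, grid, field,
                            params = agent_params(), zones = NULL,
                            max_time = 600) {
  if (is.null(zones)) zones <- decompose_zones(env)
  dests <- cfg$destinations
  if (is.null(dests)) {
    d <- env$destinations
    dests <- d$id[d$floor == 2]
  }
  set.seed(cfg$master_seed)
  headings <- stats::runif(cfg$n_samples, -180, 180)
  out <- vector("list", cfg$n_samples)
  for (i in seq_len(cfg$n_samples)) {
    ## consecutive samples share an agent id across the destination cycle,
    ## so each simulated agent contributes one trial per destination and the
    ## per-agent random intercept of the difference model is identifiable
    out[[i]] <- run_trial(cfg$agent_type, env, grid, field,
                          dests[(i - 1) %% length(dests) + 1],
                          initial_heading = headings[i],
                          seed = (cfg$master_seed + i) %% 2147483647L,
                          params = params, zones = zones,
                          max_time = max_time,
                          agent_id = sprintf("%s_%04d", cfg$agent_type,
                                             (i - 1) %/% length(dests) + 1))
  }
  out
}

#' L1 differences between agent trials and human benchmarks
#'
#' For every agent trial, the difference record is the absolute deviation of
#' its time-to-escalator and average cosine similarity from the human
#' benchmark of the same destination (the mean, or optionally median, over
#' that destination's human trials). Destinations without human trials are
#' dropped with a message.
#'
#' @param agent_measures measures data frame for agent trials (needs
#'   \code{source}, \code{subject_id}, \code{destination_id} and the two
#'   measures).
#' @param human_measures measures data frame for the benchmark trials.
#' @param stat benchmark statistic, "mean" or "median".
#' @return data frame with columns agent_id, agent_type, destination_id,
#'   diff_time, diff_cos.
#' @export
benchmark_differences <- function(agent_measures, human_measures,
                                  stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else stats::median
  bench_t <- tapply(human_measures$time_to_escalator,
                    human_measures$destination_id, f)
  bench_c <- tapply(human_measures$avg_cosine_similarity,
                    human_measures$destination_id, f)
  keep <- agent_measures$destination_id %in% names(bench_t)
  if (any(!keep))
    message(sum(!keep), " agent trial(s) dropped: no human benchmark for ",
            "their destination")
  a <- agent_measures[keep, ]
  data.frame(
    agent_id = a$subject_id,
    agent_type = ifelse(a$source == "shortest_path_agent",
                        "shortest_path", "cognitive"),
    destination_id = a$destination_id,
    diff_time = abs(a$time_to_escalator -
                      as.numeric(bench_t[a$destination_id])),
    diff_cos = abs(a$avg_cosine_similarity -
                     as.numeric(bench_c[a$destination_id])),
    stringsAsFactors = FALSE)
}

#' Mixed model on agent-minus-human differences
#'
#' Fits DifferenceInMeasure ~ AgentType + (1 | Agent) with the cognitive
#' agent as reference, so a positive AgentType coefficient means the
#' shortest-path agent deviates more from the human benchmark.
#'
#' @param diffs output of \code{\link{benchmark_differences}}.
#' @param response "diff_time" or "diff_cos".
#' @return a \code{wv_lmer}.
#' @export
agent_difference_lmer <- function(diffs, response = c("diff_time",
                                                      "diff_cos")) {
  response <- match.arg(response)
  d <- diffs
  d$AgentType <- factor(d$agent_type, levels = c("cognitive",
                                                 "shortest_path"))
  d$Agent <- factor(d$agent_id)
  fit_lmer(d, response, "AgentType", "Agent")
}

#' Spatial kernel-density raster of trajectory positions
#'
#' Gaussian KDE over the horizontal positions of all samples of the supplied
#' trajectories, evaluated on a regular raster and normalized so the cell
#' masses sum to one.
#'
#' @param trajs list of \code{wv_trajectory} (or one).
#' @param extent c(x0, x1, y0, y1); default covers the samples.
#' @param resolution raster cell size in meters.
#' @param bandwidth kernel bandwidth in meters (scalar or length 2); the
#'   default is the normal reference rule per axis.
#' @return object of class \code{wv_density_raster}: x/y cell centers,
#'   density matrix (cell masses summing to 1), bandwidth.
#' @export
spatial_kde <- function(trajs, extent = NULL, resolution = 0.5,
                        bandwidth = NULL) {
  if (inherits(trajs, "wv_trajectory")) trajs <- list(trajs)
  if (!length(trajs)) stop("no trajectories supplied")
  xs <- unlist(lapply(trajs, function(tr) tr$samples$x))
  ys <- unlist(lapply(trajs, function(tr) tr$samples$y))
  if (!length(xs)) stop("no samples to estimate from")
  if (is.null(extent))
    extent <- c(min(xs) - 2, max(xs) + 2, min(ys) - 2, max(ys) + 2)
  if (is.null(bandwidth)) {
    bw <- c(MASS::bandwidth.nrd(xs), MASS::bandwidth.nrd(ys))
    bw[bw <= 0] <- resolution          # degenerate spread: fall back
  } else bw <- rep(bandwidth, length.out = 2)
  nx <- max(2L, ceiling((extent[2] - extent[1]) / resolution))
  ny <- max(2L, ceiling((extent[4] - extent[3]) / resolution))
  k <- MASS::kde2d(xs, ys, h = bw, n = c(nx, ny),
                   lims = extent)
  cell <- diff(k$x[1:2]) * diff(k$y[1:2])
  mass <- k$z * cell
  mass <- mass / sum(mass)
  structure(list(x = k$x, y = k$y, z = mass, bandwidth = bw,
                 extent = extent),
            class = "wv_density_raster")
}

#' Export a density raster as an ESRI ASCII grid
#'
#' @param raster a \code{wv_density_raster}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_density_asc <- function(raster, path) {
  nx <- length(raster$x); ny <- length(raster$y)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", nx), sprintf("nrows %d", ny),
               sprintf("xllcorner %g", min(raster$x)),
               sprintf("yllcorner %g", min(raster$y)),
               sprintf("cellsize %g", diff(raster$x[1:2])),
               "NODATA_value -9999"), con)
  for (iy in rev(seq_len(ny)))
    writeLines(paste(format(raster$z[, iy], trim = TRUE), collapse = " "),
               con)
  invisible(path)
}

#' Dynamic time warping distance between two trajectories
#'
#' Classic unconstrained DTW on the horizontal (x, y) sample positions with
#' Euclidean local cost; symmetric, and zero for identical trajectories.
#'
#' @param a,b \code{wv_trajectory} objects or n x 2 matrices of positions.
#' @return DTW distance in meters (sum of matched local costs along the
#'   optimal warping path).
#' @export
dtw_distance <- function(a, b) {
  pa <- if (inherits(a, "wv_trajectory"))
    cbind(a$samples$x, a$samples$y) else a
  pb <- if (inherits(b, "wv_trajectory"))
    cbind(b$samples$x, b$samples$y) else b
  n <- nrow(pa); m <- nrow(pb)
  if (!n || !m) stop("empty trajectory")
  local <- outer(seq_len(n), seq_len(m), function(i, j)
    sqrt((pa[i, 1] - pb[j, 1])^2 + (pa[i, 2] - pb[j, 2])^2))
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    prev <- D[i, ]
    cur <- D[i + 1, ]
    for (j in seq_len(m)) {
      cur[j + 1] <- local[i, j] + min(prev[j], prev[j + 1], cur[j])
    }
    D[i + 1, ] <- cur
  }
  D[n + 1, m + 1]
}
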