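## Environment JSON serialization and run configuration. All coordinates in
## the JSON schema are meters in the package's internal convention
## (right-handed, z-up, yaw counter-clockwise from +x).

#' Write an environment to JSON
#'
#' The schema mirrors the in-memory structure: params, floors, walls, slab
#' (outer ring + atrium holes), atria, fence, destinations, escalator,
#' entrance and per-floor walkable rectangles.
#'
#' @param env a \code{wv_environment}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_environment <- function(env, path) {
  x <- unclass(env)
  x$footprint <- poly_to_list(env$footprint)
  x$atria <- lapply(env$atria, poly_to_list)
  x$slab <- list(z = env$slab$z, outer = poly_to_list(env$slab$outer),
                 holes = lapply(env$slab$holes, poly_to_list))
  x$escalator <- list(base = env$escalator$base, top = env$escalator$top,
                      polyline = poly_to_list(env$escalator$polyline))
  x$walkable <- lapply(env$walkable, function(fl) lapply(fl, as.numeric))
  x$params <- unclass(env$params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

poly_to_list <- function(m)
  lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))

list_to_poly <- function(l) do.call(rbind, lapply(l, as.numeric))

#' Read an environment from JSON
#'
#' Validates the loaded object against the environment invariants.
#'
#' @param path JSON file written by \code{\link{write_environment}}.
#' @return a \code{wv_environment}.
#' @export
read_environment <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("atria_type", "params", "footprint", "floors", "walls", "slab",
            "atria", "destinations", "escalator", "entrance", "walkable")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("environment JSON missing field(s): ",
         paste(missing, collapse = ", "))
  env <- list(
    atria_type = x$atria_type,
    params = structure(lapply(x$params, as.numeric),
                       class = "wv_building_params"),
    footprint = list_to_poly(x$footprint),
    floors = lapply(x$floors, function(f)
      list(id = f$id, elevation = f$elevation, ceiling = f$ceiling)),
    walls = do.call(rbind, lapply(x$walls, as.data.frame)),
    slab = list(z = x$slab$z, outer = list_to_poly(x$slab$outer),
                holes = lapply(x$slab$holes, list_to_poly)),
    atria = lapply(x$atria, list_to_poly),
    fence = if (is.null(x$fence)) NULL else as.numeric(x$fence),
    destinations = do.call(rbind, lapply(x$destinations, as.data.frame)),
    escalator = list(base = as.numeric(x$escalator$base),
                     top = as.numeric(x$escalator$top),
                     polyline = list_to_poly(x$escalator$polyline)),
    entrance = lapply(x$entrance, as.numeric),
    walkable = lapply(x$walkable, function(fl) lapply(fl, as.numeric))
  )
  class(env) <- "wv_environment"
  validate_environment(env)
  env
}

#' Assemble a run configuration
#'
#' A fully serializable record of everything a run depends on; archived next
#' to the run's outputs so any result can be regenerated.
#'
#' @param atria_type building layout.
#' @param resolution navigation grid resolution (m).
#' @param arrival_radius analysis-window arrival radius (m).
#' @param n_rays visibility rays per sample.
#' @param agent agent parameter overrides (named list).
#' @param monte_carlo Monte-Carlo settings (named list).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return list of class \code{wv_config}.
#' @export
run_config <- function(atria_type = "centralized", resolution = 1,
                       arrival_radius = 0.5, n_rays = 100,
                       agent = list(), monte_carlo = list(), seed = 1L,
                       out_dir = ".") {
  structure(list(atria_type = atria_type, resolution = resolution,
                 arrival_radius = arrival_radius, n_rays = n_rays,
                 agent = agent, monte_carlo = monte_carlo,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "wv_config")
}

#' @rdname run_config
#' @param config a \code{wv_config}.
#' @param path file path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[setdiff(names(x), character(0))])
}
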