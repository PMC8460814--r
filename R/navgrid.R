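## Navigation grid: square cells per floor, 8-connected with sqrt(2) diagonal
## cost and no corner-cutting, joined across floors by a single escalator
## link whose cost is the ramp length.

#' Build a navigation grid over an environment
#'
#' Cells are square with side \code{resolution}; a cell is walkable when its
#' center lies inside the floor's walkable area. The two floors are joined by
#' one link edge from the walkable cell nearest the escalator base to the
#' walkable cell nearest the escalator top, weighted by the ramp polyline
#' length.
#'
#' @param env a \code{wv_environment}.
#' @param resolution cell side in meters.
#' @return an object of class \code{wv_navgrid}.
#' @export
build_nav_grid <- function(env, resolution = 1) {
  stopifnot(resolution > 0)
  min_corridor <- min(vapply(unlist(env$walkable, recursive = FALSE),
                             function(r) min(r[3] - r[1], r[4] - r[2]),
                             numeric(1)))
  if (resolution > min_corridor)
    warning(sprintf(paste0("resolution (%g m) exceeds the narrowest walkable",
                           " extent (%g m); the grid may be disconnected"),
                    resolution, min_corridor))
  floors <- list()
  offset <- 0L
  for (f in 1:2) {
    bb <- do.call(rbind, env$walkable[[f]])
    x0 <- min(bb[, 1]); y0 <- min(bb[, 2])
    x1 <- max(bb[, 3]); y1 <- max(bb[, 4])
    nx <- max(1L, ceiling((x1 - x0) / resolution - 1e-9))
    ny <- max(1L, ceiling((y1 - y0) / resolution - 1e-9))
    cx <- x0 + (rep(seq_len(nx), times = ny) - 0.5) * resolution
    cy <- y0 + (rep(seq_len(ny), each = nx) - 0.5) * resolution
    walk <- point_walkable(env, f, cx, cy)
    floors[[f]] <- list(floor = f, res = resolution, x0 = x0, y0 = y0,
                        nx = nx, ny = ny, cx = cx, cy = cy, walk = walk,
                        offset = offset,
                        elevation = env$floors[[f]]$elevation)
    offset <- offset + as.integer(nx * ny)
  }
  g <- list(floors = floors, n = offset, resolution = resolution)
  ## global per-cell lookups
  g$cell_floor <- c(rep(1L, floors[[1]]$nx * floors[[1]]$ny),
                    rep(2L, floors[[2]]$nx * floors[[2]]$ny))
  g$cell_x <- c(floors[[1]]$cx, floors[[2]]$cx)
  g$cell_y <- c(floors[[1]]$cy, floors[[2]]$cy)
  g$walk <- c(floors[[1]]$walk, floors[[2]]$walk)
  g$cell_z <- ifelse(g$cell_floor == 1L, floors[[1]]$elevation,
                     floors[[2]]$elevation)
  ## escalator link
  g$base_cell <- nearest_cell_internal(g, 1L, env$escalator$base[1],
                                       env$escalator$base[2])
  g$top_cell <- nearest_cell_internal(g, 2L, env$escalator$top[1],
                                      env$escalator$top[2])
  g$link_cost <- polyline_length(env$escalator$polyline)
  g <- grid_adjacency(g)
  class(g) <- "wv_navgrid"
  g
}

nearest_cell_internal <- function(g, floor, x, y) {
  idx <- which(g$cell_floor == floor & g$walk)
  idx[which.min((g$cell_x[idx] - x)^2 + (g$cell_y[idx] - y)^2)]
}

#' Nearest walkable cell to a plan point
#'
#' @param grid a \code{wv_navgrid}.
#' @param floor floor number.
#' @param x,y plan coordinates.
#' @return global cell index.
#' @export
nearest_cell <- function(grid, floor, x, y) {
  nearest_cell_internal(grid, as.integer(floor), x, y)
}

## Precompute 8-connected neighbor lists. Diagonal moves are allowed only
## when both flanking orthogonal cells are walkable (no corner cutting).
grid_adjacency <- function(g) {
  nbr <- vector("list", g$n)
  cost <- vector("list", g$n)
  for (f in 1:2) {
    fl <- g$floors[[f]]
    nx <- fl$nx; ny <- fl$ny; off <- fl$offset
    walk <- matrix(fl$walk, nx, ny)
    res <- fl$res
    steps <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
    for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
      if (!walk[ix, iy]) next
      id <- off + (iy - 1L) * nx + ix
      nb <- integer(0); cs <- numeric(0)
      for (s in steps) {
        jx <- ix + s[1]; jy <- iy + s[2]
        if (jx < 1 || jx > nx || jy < 1 || jy > ny) next
        if (!walk[jx, jy]) next
        if (s[1] != 0 && s[2] != 0 &&
            (!walk[jx, iy] || !walk[ix, jy])) next
        nb <- c(nb, off + (jy - 1L) * nx + jx)
        cs <- c(cs, res * sqrt(sum(s^2)))
      }
      nbr[[id]] <- nb
      cost[[id]] <- cs
    }
  }
  ## escalator link (both directions)
  nbr[[g$base_cell]] <- c(nbr[[g$base_cell]], g$top_cell)
  cost[[g$base_cell]] <- c(cost[[g$base_cell]], g$link_cost)
  nbr[[g$top_cell]] <- c(nbr[[g$top_cell]], g$base_cell)
  cost[[g$top_cell]] <- c(cost[[g$top_cell]], g$link_cost)
  g$nbr <- nbr
  g$cost <- cost
  g
}

#' Count walkable cells
#'
#' @param grid a \code{wv_navgrid}.
#' @param floor optional floor filter.
#' @return integer count.
#' @export
n_walkable <- function(grid, floor = NULL) {
  if (is.null(floor)) sum(grid$walk)
  else sum(grid$walk & grid$cell_floor == floor)
}

#' Are two cells in the same connected component?
#'
#' Breadth-first search over the walkable graph (including the escalator
#' link).
#'
#' @param grid a \code{wv_navgrid}.
#' @param from,to global cell indices.
#' @return logical scalar.
#' @export
grid_connected <- function(grid, from, to) {
  seen <- logical(grid$n)
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) return(TRUE)
    nb <- grid$nbr[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  seen[to]
}

## Admissible heuristic. Same floor: straight-line distance. Different
## floors: any path must pass the escalator, so the bound routes through the
## link cells plus the ramp cost. The floor-1 component of the bound does not
## depend on the goal's position beyond a constant, which keeps expansion
## order on the first floor identical across second-floor goals.
astar_heuristic <- function(g, cells, goal) {
  gf <- g$cell_floor[goal]
  same <- g$cell_floor[cells] == gf
  h <- numeric(length(cells))
  h[same] <- dist2d(g$cell_x[cells[same]], g$cell_y[cells[same]],
                    g$cell_x[goal], g$cell_y[goal])
  if (any(!same)) {
    gate <- if (gf == 2L) g$base_cell else g$top_cell
    exit <- if (gf == 2L) g$top_cell else g$base_cell
    h[!same] <- dist2d(g$cell_x[cells[!same]], g$cell_y[cells[!same]],
                       g$cell_x[gate], g$cell_y[gate]) + g$link_cost +
      dist2d(g$cell_x[exit], g$cell_y[exit], g$cell_x[goal], g$cell_y[goal])
  }
  h
}

#' Shortest grid path by A*
#'
#' Optimal under the 8-connected grid metric with the Euclidean
#' (through-escalator for inter-floor queries) heuristic, which is
#' admissible and consistent. Ties on f are broken towards the smaller
#' heuristic, then the smaller cell index, making paths deterministic.
#'
#' @param grid a \code{wv_navgrid}.
#' @param from,to global cell indices (walkable).
#' @return list with \code{path} (integer cell sequence) and \code{cost}
#'   (meters); errors with class \code{wv_no_path} when unreachable.
#' @export
plan_shortest_path <- function(grid, from, to) {
  g <- grid
  stopifnot(g$walk[from], g$walk[to])
  n <- g$n
  dist <- rep(Inf, n)
  came <- integer(n)
  closed <- logical(n)
  h0 <- astar_heuristic(g, from, to)
  open <- from
  fsc <- h0
  hsc <- h0
  dist[from] <- 0
  while (length(open)) {
    k <- order(fsc, hsc, open)[1]
    v <- open[k]
    open <- open[-k]; fsc <- fsc[-k]; hsc <- hsc[-k]
    if (closed[v]) next
    closed[v] <- TRUE
    if (v == to) break
    nb <- g$nbr[[v]]
    cs <- g$cost[[v]]
    for (j in seq_along(nb)) {
      w <- nb[j]
      if (closed[w]) next
      nd <- dist[v] + cs[j]
      if (nd < dist[w] - 1e-12) {
        dist[w] <- nd
        came[w] <- v
        hw <- astar_heuristic(g, w, to)
        open <- c(open, w)
        fsc <- c(fsc, nd + hw)
        hsc <- c(hsc, hw)
      }
    }
  }
  if (!is.finite(dist[to])) {
    cond <- structure(class = c("wv_no_path", "error", "condition"),
                      list(message = "goal cell unreachable", call = NULL))
    stop(cond)
  }
  path <- to
  while (path[1] != from) path <- c(came[path[1]], path)
  list(path = path, cost = dist[to])
}
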