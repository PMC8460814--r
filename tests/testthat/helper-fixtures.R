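## Shared fixtures. The default building, grid, zones and drift field are
## built once per test run and reused (they are deterministic).

wv_cache <- new.env(parent = emptyenv())

fixture_env <- function(atria = "centralized") {
  key <- paste0("env_", atria)
  if (is.null(wv_cache[[key]])) wv_cache[[key]] <- build_building(atria)
  wv_cache[[key]]
}

fixture_grid <- function(atria = "centralized") {
  key <- paste0("grid_", atria)
  if (is.null(wv_cache[[key]]))
    wv_cache[[key]] <- build_nav_grid(fixture_env(atria), 1)
  wv_cache[[key]]
}

fixture_zones <- function(atria = "centralized") {
  key <- paste0("zones_", atria)
  if (is.null(wv_cache[[key]]))
    wv_cache[[key]] <- decompose_zones(fixture_env(atria))
  wv_cache[[key]]
}

fixture_field <- function(atria = "centralized") {
  key <- paste0("field_", atria)
  if (is.null(wv_cache[[key]]))
    wv_cache[[key]] <- build_drift_field(fixture_grid(atria),
                                         fixture_env(atria))
  wv_cache[[key]]
}

## A hand-made single-room environment (both floors must exist; floor 2 is a
## detached 1 m pad holding the escalator top). Used for analytic visibility
## and measure oracles where the full building would obscure the arithmetic.
toy_env <- function(walk1 = list(c(0, 0, 10, 10)),
                    walls = NULL,
                    entrance = c(0.5, 0.5),
                    base = c(9, 9),
                    destinations = NULL) {
  if (is.null(walls)) {
    r <- walk1[[1]]
    walls <- data.frame(
      x1 = c(r[1], r[3], r[3], r[1]), y1 = c(r[2], r[2], r[4], r[4]),
      x2 = c(r[3], r[3], r[1], r[1]), y2 = c(r[2], r[4], r[4], r[2]),
      z0 = 0, z1 = 3, kind = "exterior", occludes = TRUE)
  }
  top <- c(base[1] + 1, base[2], 3)
  env <- list(
    atria_type = "toy",
    params = building_params(),
    footprint = rect_poly(-50, -50, 50, 50),
    floors = list(list(id = 1, elevation = 0, ceiling = 3),
                  list(id = 2, elevation = 3, ceiling = 3)),
    walls = walls,
    slab = list(z = 1000, outer = rect_poly(-1, -1, 0, 0), holes = list()),
    atria = list(),
    fence = NULL,
    destinations = destinations,
    escalator = list(base = c(base, 0), top = top,
                     polyline = rbind(c(base, 0), top)),
    entrance = list(x = entrance[1], y = entrance[2], z = 0, yaw = 0,
                    pitch = 0),
    walkable = list(walk1,
                    list(c(top[1] - 0.5, top[2] - 0.5,
                           top[1] + 0.5, top[2] + 0.5)))
  )
  class(env) <- "wv_environment"
  env
}

## a destination row for toy environments
toy_dest <- function(cx, cy, nx = -1, ny = 0, z0 = 0.5, z1 = 2.5,
                     width = 2, floor = 1, facing = "forward") {
  data.frame(id = "toy", floor = floor, facing = facing, side = "left",
             cx = cx, cy = cy, z0 = z0, z1 = z1, width = width,
             nx = nx, ny = ny, stringsAsFactors = FALSE)
}

## Dense-sweep isovist area/centroid oracle: many thin triangular sectors.
## Independent of the polygon construction in the implementation.
dense_isovist_oracle <- function(ox, oy, segs, range = 100, step = 0.01) {
  ang <- deg2rad_t(seq(0, 360 - step, by = step))
  n <- length(ang)
  dx <- cos(ang); dy <- sin(ang)
  tmin <- rep(range, n)
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      ax <- segs[i, 1]; ay <- segs[i, 2]
      wx <- segs[i, 3] - ax; wy <- segs[i, 4] - ay
      den <- dx * wy - dy * wx
      t <- ((ax - ox) * wy - (ay - oy) * wx) / den
      s <- ((ax - ox) * dy - (ay - oy) * dx) / den
      hit <- abs(den) > 1e-12 & t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
      tmin[hit] <- pmin(tmin[hit], t[hit])
    }
  }
  dth <- deg2rad_t(step)
  a_sec <- 0.5 * tmin^2 * dth                  # sector areas
  r_cen <- 2 / 3 * tmin                        # sector centroid radius
  area <- sum(a_sec)
  cx <- ox + sum(a_sec * r_cen * dx) / area
  cy <- oy + sum(a_sec * r_cen * dy) / area
  list(area = area, centroid = c(cx, cy))
}

deg2rad_t <- function(d) d * pi / 180

## random rectangular room with 0-2 rectangular columns, plus wall segments
random_room <- function(seed) {
  set.seed(seed)
  w <- runif(1, 6, 16); h <- runif(1, 6, 16)
  segs <- rbind(c(0, 0, w, 0), c(w, 0, w, h), c(w, h, 0, h), c(0, h, 0, 0))
  ncol <- sample(0:2, 1)
  cols <- list()
  for (k in seq_len(ncol)) {
    cw <- runif(1, 0.5, 2); ch <- runif(1, 0.5, 2)
    cx <- runif(1, 1.5, w - 1.5 - cw); cy <- runif(1, 1.5, h - 1.5 - ch)
    segs <- rbind(segs,
                  c(cx, cy, cx + cw, cy), c(cx + cw, cy, cx + cw, cy + ch),
                  c(cx + cw, cy + ch, cx, cy + ch), c(cx, cy + ch, cx, cy))
    cols[[k]] <- c(cx, cy, cx + cw, cy + ch)
  }
  ## an origin in free space
  repeat {
    ox <- runif(1, 0.8, w - 0.8); oy <- runif(1, 0.8, h - 0.8)
    inside <- any(vapply(cols, function(r)
      ox > r[1] - 0.3 && ox < r[3] + 0.3 && oy > r[2] - 0.3 &&
        oy < r[4] + 0.3, logical(1)))
    if (!inside) break
  }
  list(segs = segs, origin = c(ox, oy), w = w, h = h, cols = cols)
}

## random 8x8 single-floor grid object for A*-vs-Dijkstra checks
random_toy_grid <- function(seed, nx = 8, ny = 8, p_block = 0.25) {
  set.seed(seed)
  walk <- matrix(runif(nx * ny) > p_block, nx, ny)
  walk[1, 1] <- TRUE; walk[nx, ny] <- TRUE
  g <- list(
    floors = list(list(floor = 1, res = 1, x0 = 0, y0 = 0, nx = nx, ny = ny,
                       cx = rep(seq_len(nx) - 0.5, times = ny),
                       cy = rep(seq_len(ny) - 0.5, each = nx),
                       walk = as.vector(walk), offset = 0L, elevation = 0),
                  list(floor = 2, res = 1, x0 = 100, y0 = 100, nx = 1,
                       ny = 1, cx = 100.5, cy = 100.5, walk = TRUE,
                       offset = as.integer(nx * ny), elevation = 3)),
    n = as.integer(nx * ny + 1), resolution = 1)
  g$cell_floor <- c(rep(1L, nx * ny), 2L)
  g$cell_x <- c(g$floors[[1]]$cx, 100.5)
  g$cell_y <- c(g$floors[[1]]$cy, 100.5)
  g$walk <- c(as.vector(walk), TRUE)
  g$cell_z <- c(rep(0, nx * ny), 3)
  first_walk <- which(as.vector(walk))[1]
  g$base_cell <- first_walk
  g$top_cell <- as.integer(nx * ny + 1)
  g$link_cost <- 5
  g <- wayvis:::grid_adjacency(g)
  class(g) <- "wv_navgrid"
  g
}

## Dijkstra over the same adjacency using igraph (independent oracle)
dijkstra_cost <- function(g, from, to) {
  edges <- list(); weights <- numeric(0)
  for (v in seq_len(g$n)) {
    nb <- g$nbr[[v]]
    if (is.null(nb) || !length(nb)) next
    for (j in seq_along(nb)) {
      edges[[length(edges) + 1]] <- c(v, nb[j])
      weights <- c(weights, g$cost[[v]][j])
    }
  }
  em <- do.call(rbind, edges)
  ig <- igraph::graph_from_edgelist(em, directed = TRUE)
  igraph::distances(ig, v = from, to = to, weights = weights,
                    mode = "out")[1, 1]
}
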