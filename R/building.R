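## Parametric two-floor study building: a rectangular footprint with enclosed
## rooms along the first-floor perimeter, a central open corridor, a single
## escalator to the second floor, and an upper-floor slab perforated by either
## one centralized atrium or three distributed atria of equal total area.

#' Building parameters
#'
#' All dimensions are in meters. Defaults give a 36 x 18 m footprint with a
#' 3 m floor-to-floor height and a total atrium void area of 288 m^2 for both
#' atria layouts. The footprint proportions are a documented default, not a
#' claim about any particular real building; only the atrium area is treated
#' as a hard constraint.
#'
#' @param floor_length footprint extent along x (entrance wall at x = 0).
#' @param floor_width footprint extent along y, centered on y = 0.
#' @param floor_height floor-to-floor height (second-floor elevation).
#' @param ceiling_height clear height of each floor.
#' @param room_depth depth of the perimeter room bands on the first floor.
#' @param atria_area total atrium void area cut from the second-floor slab.
#' @param atria_void_depth y-extent of the atrium voids.
#' @param atria_gap slab strip width between distributed atria.
#' @param door_width,door_height destination door dimensions.
#' @param eye_height eye height used for isovists and visibility.
#' @return a list of class \code{wv_building_params}.
#' @export
building_params <- function(floor_length = 36, floor_width = 18,
                            floor_height = 3, ceiling_height = 3,
                            room_depth = 4, atria_area = 288,
                            atria_void_depth = 12, atria_gap = 1,
                            door_width = 1, door_height = 2,
                            eye_height = 1.7) {
  p <- list(floor_length = floor_length, floor_width = floor_width,
            floor_height = floor_height, ceiling_height = ceiling_height,
            room_depth = room_depth, atria_area = atria_area,
            atria_void_depth = atria_void_depth, atria_gap = atria_gap,
            door_width = door_width, door_height = door_height,
            eye_height = eye_height)
  stopifnot(all(vapply(p, is.numeric, logical(1))), all(unlist(p) > 0))
  if (floor_width <= 2 * room_depth)
    stop("floor_width must exceed twice room_depth")
  class(p) <- "wv_building_params"
  p
}

#' Build a study environment
#'
#' Constructs the multilevel walkable geometry for one of the two atria
#' layouts. The first floor (perimeter rooms, corridor, destinations,
#' entrance, escalator) is identical across layouts; the layouts differ only
#' in the second-floor atrium voids and the movement fence.
#'
#' Eight destination doors are placed, four per floor, two
#' "entrance-forward-facing" (door surface oriented towards the entrance) and
#' two "entrance-backwards-facing" (door surface oriented away from the
#' entrance) per floor, one of each on the left and right of the entrance
#' heading.
#'
#' @param atria_type \code{"centralized"} (one atrium) or
#'   \code{"distributed"} (three atria).
#' @param params a \code{\link{building_params}} object.
#' @param allow_area_mismatch keep an \code{atria_area} that cannot be tiled
#'   exactly instead of erroring.
#' @return an object of class \code{wv_environment}.
#' @export
build_building <- function(atria_type = c("centralized", "distributed"),
                           params = building_params(),
                           allow_area_mismatch = FALSE) {
  atria_type <- match.arg(atria_type)
  p <- params
  ## the 288 m^2 total void area is the study constant; departing from it is
  ## an explicit opt-in, not a silent parameter change
  if (abs(p$atria_area - 288) > 1e-6 && !allow_area_mismatch)
    stop("atria_area differs from the 288 m^2 study default; set ",
         "allow_area_mismatch = TRUE to build a variant environment")
  L <- p$floor_length; W <- p$floor_width; H <- p$floor_height
  hw <- W / 2
  cw <- hw - p$room_depth                       # corridor half-width
  footprint <- rect_poly(0, -hw, L, hw)

  ## ---- atria voids (cut from the second-floor slab) --------------------
  vd <- p$atria_void_depth                      # void y-extent
  if (atria_type == "centralized") {
    vx <- p$atria_area / vd                     # single void x-extent
    x1 <- (L + vx) / 2                          # centered on the footprint
    x0 <- x1 - vx
    atria <- list(rect_poly(x0, -vd / 2, x1, vd / 2))
    inner <- c(x0, -vd / 2, x1, vd / 2)
    fence <- NULL
  } else {
    each <- p$atria_area / 3
    vx <- each / vd
    ## rightmost void flush with the centralized void's east edge so the
    ## escalator ramp rises through open air in both layouts
    xe <- (L + p$atria_area / vd) / 2
    starts <- xe - vx - (2:0) * (vx + p$atria_gap)
    atria <- lapply(starts, function(s) rect_poly(s, -vd / 2, s + vx, vd / 2))
    inner <- c(starts[1], -vd / 2, xe, vd / 2)
    fence <- inner                              # movement-only barrier
  }
  got <- sum(vapply(atria, function(a) abs(poly_area(a)), numeric(1)))
  if (abs(got - p$atria_area) > 1e-6 * p$atria_area && !allow_area_mismatch)
    stop(sprintf("atria voids tile %.6f m^2, requested %.6f m^2", got,
                 p$atria_area))

  ## ---- walls (3D rectangles: plan segment + z-range) -------------------
  wall <- function(x1, y1, x2, y2, z0, z1, kind) {
    data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2, z0 = z0, z1 = z1,
               kind = kind, occludes = TRUE)
  }
  walls <- rbind(
    wall(0, -hw, L, -hw, 0, 2 * H, "exterior"),
    wall(L, -hw, L, hw, 0, 2 * H, "exterior"),
    wall(L, hw, 0, hw, 0, 2 * H, "exterior"),
    wall(0, hw, 0, -hw, 0, 2 * H, "exterior"),
    ## first-floor room fronts (glass doors are transparent; the destination
    ## rectangles live on these planes)
    wall(0, cw, L - p$room_depth, cw, 0, H, "room"),
    wall(0, -cw, L - p$room_depth, -cw, 0, H, "room"),
    wall(L - p$room_depth, -cw, L - p$room_depth, cw, 0, H, "room")
  )

  ## ---- destinations -----------------------------------------------------
  dw <- p$door_width; dh <- p$door_height
  dest <- function(id, floor, facing, side, cx, cy, nx, ny) {
    z0 <- if (floor == 1) 0 else H
    data.frame(id = id, floor = floor, facing = facing, side = side,
               cx = cx, cy = cy, z0 = z0, z1 = z0 + dh, width = dw,
               nx = nx, ny = ny, stringsAsFactors = FALSE)
  }
  destinations <- rbind(
    ## first floor: forward-facing on the far room front, backwards-facing on
    ## the entrance wall (behind the fixed initial heading)
    dest("F1_fwd_L", 1, "forward",  "left",  L - p$room_depth,  cw / 2, -1, 0),
    dest("F1_fwd_R", 1, "forward",  "right", L - p$room_depth, -cw / 2, -1, 0),
    dest("F1_bwd_L", 1, "backward", "left",  0,  cw * 0.7,  1, 0),
    dest("F1_bwd_R", 1, "backward", "right", 0, -cw * 0.7,  1, 0),
    ## second floor: corners of the walkable ring
    dest("F2_fwd_L", 2, "forward",  "left",  L,  hw - 1.5, -1, 0),
    dest("F2_fwd_R", 2, "forward",  "right", L, -hw + 1.5, -1, 0),
    dest("F2_bwd_L", 2, "backward", "left",  0,  hw - 1.5,  1, 0),
    dest("F2_bwd_R", 2, "backward", "right", 0, -hw + 1.5,  1, 0)
  )

  ## ---- escalator --------------------------------------------------------
  run <- 2 * H                                  # horizontal run of the ramp
  base <- c(inner[3] - run, 0, 0)               # under the void in both layouts
  brk <- c(inner[3], 0, H)
  top <- c(inner[3] + 0.5, 0, H)
  escalator <- list(base = base, top = top, polyline = rbind(base, brk, top))

  ## ---- walkable regions (axis-aligned rectangles per floor) -------------
  walk1 <- list(c(0, -cw, L - p$room_depth, cw))
  ir <- if (atria_type == "centralized") inner else fence
  walk2 <- list(c(0, -hw, ir[1], hw),            # west
                c(ir[3], -hw, L, hw),            # east
                c(ir[1], ir[4], ir[3], hw),      # north
                c(ir[1], -hw, ir[3], ir[2]))     # south

  env <- list(
    atria_type = atria_type,
    params = p,
    footprint = footprint,
    floors = list(list(id = 1, elevation = 0, ceiling = H),
                  list(id = 2, elevation = H, ceiling = p$ceiling_height)),
    walls = walls,
    slab = list(z = H, outer = footprint, holes = atria),
    atria = atria,
    fence = fence,
    destinations = destinations,
    escalator = escalator,
    entrance = list(x = 0.5, y = 0, z = 0, yaw = 0, pitch = 0),
    walkable = list(walk1, walk2)
  )
  class(env) <- "wv_environment"
  validate_environment(env)
  env
}

#' Validate an environment against its structural invariants
#'
#' Checks the atrium area budget, the destination layout (eight doors, four
#' per floor, two forward- and two backwards-facing per floor), and basic
#' escalator/entrance consistency. Called by the builder and the JSON loader.
#'
#' @param env a \code{wv_environment}.
#' @return the environment, invisibly; errors on violation.
#' @export
validate_environment <- function(env) {
  stopifnot(inherits(env, "wv_environment"))
  area <- sum(vapply(env$atria, function(a) abs(poly_area(a)), numeric(1)))
  if (abs(area - env$params$atria_area) > 1e-6 * env$params$atria_area)
    stop("total atrium void area violates the area budget")
  d <- env$destinations
  if (nrow(d) != 8) stop("expected 8 destinations")
  for (f in 1:2) {
    df <- d[d$floor == f, ]
    if (nrow(df) != 4 || sum(df$facing == "forward") != 2 ||
        sum(df$facing == "backward") != 2)
      stop("each floor needs 4 destinations, 2 forward- and 2 backwards-facing")
  }
  if (!point_walkable(env, 1, env$entrance$x, env$entrance$y))
    stop("entrance is not on walkable floor area")
  if (!point_walkable(env, 1, env$escalator$base[1], env$escalator$base[2]))
    stop("escalator base is not on walkable first-floor area")
  if (!point_walkable(env, 2, env$escalator$top[1], env$escalator$top[2]))
    stop("escalator top is not on walkable second-floor area")
  invisible(env)
}

#' Is a plan point on walkable floor area?
#'
#' @param env a \code{wv_environment}.
#' @param floor floor number (1 or 2).
#' @param x,y plan coordinates (vectorized).
#' @return logical vector.
#' @export
point_walkable <- function(env, floor, x, y) {
  out <- rep(FALSE, length(x))
  for (r in env$walkable[[floor]])
    out <- out | (x >= r[1] & x <= r[3] & y >= r[2] & y <= r[4])
  out
}

## total walkable area of one floor (sum of the disjoint walkable rectangles)
walkable_area <- function(env, floor) {
  sum(vapply(env$walkable[[floor]],
             function(r) (r[3] - r[1]) * (r[4] - r[2]), numeric(1)))
}

#' @export
print.wv_environment <- function(x, ...) {
  cat(sprintf("<wv_environment: %s atria>\n", x$atria_type))
  cat(sprintf("  footprint %g x %g m, %d atrium void(s), total %.1f m^2\n",
              x$params$floor_length, x$params$floor_width, length(x$atria),
              sum(vapply(x$atria, function(a) abs(poly_area(a)), numeric(1)))))
  cat(sprintf("  %d destinations, escalator base (%.1f, %.1f)\n",
              nrow(x$destinations), x$escalator$base[1], x$escalator$base[2]))
  invisible(x)
}

#' Decompose the walkable area into convex zones
#'
#' Zones are the agent's coarse spatial memory unit: convex plan polygons
#' (extruded conceptually to the floor's ceiling) that tile the walkable area
#' of each floor exactly. The builder's walkable regions are unions of
#' axis-aligned rectangles, which are partitioned and then subdivided so that
#' no zone extends more than \code{max_extent} meters in either axis; this
#' caps zone size at roughly room scale, which is the granularity at which
#' the agent's visited-zone memory operates.
#'
#' @param env a \code{wv_environment}.
#' @param max_extent maximum zone extent per axis, in meters.
#' @return a data frame of class \code{wv_zones} with one row per zone:
#'   id, floor, x0, y0, x1, y1, and an \code{adjacency} attribute (list of
#'   integer vectors).
#' @export
decompose_zones <- function(env, max_extent = 8) {
  rows <- list()
  for (f in 1:2) {
    for (r in env$walkable[[f]]) {
      nx <- max(1, ceiling((r[3] - r[1]) / max_extent))
      ny <- max(1, ceiling((r[4] - r[2]) / max_extent))
      xs <- seq(r[1], r[3], length.out = nx + 1)
      ys <- seq(r[2], r[4], length.out = ny + 1)
      for (i in seq_len(nx)) for (j in seq_len(ny))
        rows[[length(rows) + 1]] <-
          data.frame(floor = f, x0 = xs[i], y0 = ys[j],
                     x1 = xs[i + 1], y1 = ys[j + 1])
    }
  }
  z <- do.call(rbind, rows)
  z$id <- seq_len(nrow(z))
  z <- z[, c("id", "floor", "x0", "y0", "x1", "y1")]
  n <- nrow(z)
  adj <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || z$floor[i] != z$floor[j]) next
    xov <- min(z$x1[i], z$x1[j]) - max(z$x0[i], z$x0[j])
    yov <- min(z$y1[i], z$y1[j]) - max(z$y0[i], z$y0[j])
    touch <- (abs(xov) < 1e-9 && yov > 1e-9) ||
             (abs(yov) < 1e-9 && xov > 1e-9)
    if (touch) adj[[i]] <- c(adj[[i]], j)
  }
  attr(z, "adjacency") <- adj
  class(z) <- c("wv_zones", "data.frame")
  z
}

#' Zone membership of plan points
#'
#' @param zones a \code{wv_zones} data frame.
#' @param floor floor number (scalar).
#' @param x,y plan coordinates (vectorized).
#' @return integer vector of zone ids (NA outside all zones).
#' @export
zone_of <- function(zones, floor, x, y) {
  out <- rep(NA_integer_, length(x))
  zf <- zones[zones$floor == floor, ]
  for (k in seq_len(nrow(zf))) {
    hit <- is.na(out) & x >= zf$x0[k] & x <= zf$x1[k] &
      y >= zf$y0[k] & y <= zf$y1[k]
    out[hit] <- zf$id[k]
  }
  out
}
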