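## Visibility engine: ray-cast destination visibility bounded by a 3D field
## of view, 2D isovists at eye height, the isovist drift measure, and the
## precomputed per-cell drift field that steers the cognitive agent's
## exploration.

#' Field-of-view specification
#'
#' @param horizontal horizontal opening angle in degrees, in (0, 360].
#' @param vertical vertical opening angle in degrees, in (0, 360].
#' @param range view range in meters.
#' @return object of class \code{wv_fov}.
#' @export
field_of_view <- function(horizontal = 360, vertical = 180, range = 100) {
  stopifnot(horizontal > 0, horizontal <= 360, vertical > 0, vertical <= 360,
            range > 0)
  structure(list(horizontal = horizontal, vertical = vertical, range = range),
            class = "wv_fov")
}

#' Default field of view for the desktop observer
#'
#' A 16:9 desktop camera with a 60 degree vertical opening (horizontal about
#' 91 degrees), used when scoring destination visibility along human or
#' synthetic trajectories. Override per analysis if the recording camera
#' differed.
#'
#' @return a \code{wv_fov}.
#' @export
observer_fov <- function() field_of_view(horizontal = 91, vertical = 60,
                                         range = 100)

#' Default field of view for the cognitive agent
#'
#' Horizontal opening 150 degrees, view range 100 m; the vertical opening is
#' a model parameter defaulting to 60 degrees.
#'
#' @param vertical vertical opening in degrees.
#' @return a \code{wv_fov}.
#' @export
agent_fov <- function(vertical = 60) field_of_view(horizontal = 150,
                                                   vertical = vertical,
                                                   range = 100)

## Wall segments that occlude sight at a given eye height (projected to 2D).
wall_segments <- function(env, eye_z) {
  w <- env$walls
  w <- w[w$occludes & w$z0 < eye_z & w$z1 > eye_z, , drop = FALSE]
  cbind(w$x1, w$y1, w$x2, w$y2)
}

## Cast rays from a 2D origin at the given absolute angles (radians) against
## segments; returns the hit distance per ray, capped at `range`.
cast_rays <- function(ox, oy, angles, segs, range) {
  dx <- cos(angles); dy <- sin(angles)
  tmin <- rep(range, length(angles))
  if (nrow(segs)) {
    ax <- segs[, 1]; ay <- segs[, 2]
    wx <- segs[, 3] - ax; wy <- segs[, 4] - ay
    for (i in seq_along(angles)) {
      den <- dx[i] * wy - dy[i] * wx
      ok <- abs(den) > 1e-12
      t <- ((ax - ox) * wy - (ay - oy) * wx) / den
      s <- ((ax - ox) * dy[i] - (ay - oy) * dx[i]) / den
      hit <- ok & t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
      if (any(hit)) tmin[i] <- min(tmin[i], t[hit])
    }
  }
  tmin
}

#' Compute a 2D isovist
#'
#' The visible-area polygon around a vantage point at eye height, bounded by
#' occluding walls and the view-range circle. Rays are cast at the stated
#' angular resolution plus extra rays aimed just either side of every
#' occluder endpoint, so polygon corners are captured essentially exactly;
#' the range circle is approximated at the angular resolution.
#'
#' @param origin numeric (x, y, z); z selects the floor and must be at eye
#'   level inside that floor's volume.
#' @param env a \code{wv_environment}.
#' @param fov a \code{wv_fov}; the default is the full-circle isovist with a
#'   100 m range.
#' @param angular_resolution sweep step in degrees.
#' @param heading view direction in degrees (ignored for 360 degree fov).
#' @return object of class \code{wv_isovist} with fields origin, polygon,
#'   area, centroid.
#' @export
compute_isovist <- function(origin, env, fov = field_of_view(360, 180, 100),
                            angular_resolution = 1, heading = 0) {
  stopifnot(angular_resolution > 0)
  fl <- which(vapply(env$floors, function(f)
    origin[3] >= f$elevation & origin[3] < f$elevation + f$ceiling,
    logical(1)))[1]
  if (is.na(fl)) stop("origin z outside all floor volumes")
  if (!point_walkable(env, fl, origin[1], origin[2]))
    stop("isovist origin is not on walkable area (inside an occluder?)")
  segs <- wall_segments(env, origin[3])
  iso_from_segments(origin[1], origin[2], segs, fov$horizontal, heading,
                    fov$range, angular_resolution, origin = origin)
}

## Core 2D sweep shared by compute_isovist and tests on raw wall sets.
iso_from_segments <- function(ox, oy, segs, fov_h = 360, heading = 0,
                              range = 100, ares = 1, origin = c(ox, oy, NA)) {
  full <- fov_h >= 360 - 1e-9
  if (full) {
    ang <- seq(0, 360 - ares, by = ares)
  } else {
    ang <- seq(heading - fov_h / 2, heading + fov_h / 2, by = ares)
  }
  eps <- 1e-6
  if (nrow(segs)) {
    pts <- rbind(segs[, 1:2], segs[, 3:4])
    ea <- rad2deg(atan2(pts[, 2] - oy, pts[, 1] - ox))
    ang <- c(ang, ea - eps, ea + eps)
  }
  ang <- ang %% 360
  if (!full) {
    rel <- normalize_angle(ang - heading)
    keep <- abs(rel) <= fov_h / 2 + 1e-12
    ## order by angle relative to the heading so a wedge crossing 0 degrees
    ## still yields a correctly ordered fan polygon
    ang <- ang[keep][order(rel[keep])]
    ang <- ang[c(TRUE, diff(ang %% 360) != 0)]
  } else {
    ang <- sort(unique(ang))
  }
  rad <- deg2rad(ang)
  t <- cast_rays(ox, oy, rad, segs, range)
  poly <- cbind(ox + t * cos(rad), oy + t * sin(rad))
  if (!full) poly <- rbind(c(ox, oy), poly)
  structure(list(origin = origin, polygon = poly,
                 area = abs(poly_area(poly)),
                 centroid = poly_centroid(poly)),
            class = "wv_isovist")
}

#' Isovist drift
#'
#' Distance in meters between the isovist's casting origin and the area
#' centroid ("center of gravity") of its polygon. Drift approaches zero at
#' the centers of open spaces and along corridor center-lines.
#'
#' @param iso a \code{wv_isovist}.
#' @return drift in meters (non-negative).
#' @export
isovist_drift <- function(iso) {
  stopifnot(inherits(iso, "wv_isovist"))
  as.numeric(dist2d(iso$origin[1], iso$origin[2],
                    iso$centroid[1], iso$centroid[2]))
}

#' Precompute the drift field over a navigation grid
#'
#' Casts a full-circle isovist from every walkable cell center at eye height
#' and stores the drift of each. The agent reads this field through its
#' field of view during exploration.
#'
#' @param grid a \code{wv_navgrid}.
#' @param env the matching \code{wv_environment}.
#' @param fov isovist field of view (full circle, 100 m by default).
#' @param angular_resolution sweep step in degrees.
#' @return object of class \code{wv_drift_field}: numeric drift per global
#'   cell (NA for unwalkable cells) plus parameters.
#' @export
build_drift_field <- function(grid, env, fov = field_of_view(360, 180, 100),
                              angular_resolution = 2) {
  drift <- rep(NA_real_, grid$n)
  eye <- env$params$eye_height
  for (f in 1:2) {
    eye_z <- env$floors[[f]]$elevation + eye
    segs <- wall_segments(env, eye_z)
    idx <- which(grid$cell_floor == f & grid$walk)
    for (i in idx) {
      iso <- iso_from_segments(grid$cell_x[i], grid$cell_y[i], segs,
                               360, 0, fov$range, angular_resolution,
                               origin = c(grid$cell_x[i], grid$cell_y[i],
                                          eye_z))
      drift[i] <- isovist_drift(iso)
    }
  }
  structure(list(drift = drift, fov = fov,
                 angular_resolution = angular_resolution,
                 resolution = grid$resolution),
            class = "wv_drift_field")
}

#' Drift value at a walkable cell
#'
#' @param field a \code{wv_drift_field}.
#' @param cell global cell index.
#' @return drift in meters; errors on unwalkable cells.
#' @export
drift_at <- function(field, cell) {
  v <- field$drift[cell]
  if (anyNA(v)) stop("drift queried at an unwalkable cell")
  v
}

#' Ray-cast destination visibility from a pose
#'
#' Casts a uniform k x k grid of rays from the eye point to the destination
#' door rectangle and reports the fraction reaching it. A ray reaches the
#' door when its target point lies inside the field-of-view cone (yaw and
#' pitch half-angles) and the view range, approaches the door from its front
#' side, and is not intercepted by a wall or by the second-floor slab
#' (atrium voids are holes in the slab; glass doors are transparent).
#'
#' @param pose list or vector with x, y, z (floor elevation), yaw, pitch in
#'   degrees.
#' @param dest a destination id (string) or a row of
#'   \code{env$destinations}.
#' @param env a \code{wv_environment}.
#' @param fov a \code{wv_fov}.
#' @param n_rays requested ray count; rounded down to a square number.
#' @param eye_height eye height above \code{pose$z}.
#' @return object of class \code{wv_visibility_sample} with
#'   \code{fraction_visible}, \code{n_rays_cast}, \code{n_rays_reaching}.
#' @export
destination_visibility <- function(pose, dest, env, fov = observer_fov(),
                                   n_rays = 100,
                                   eye_height = env$params$eye_height) {
  stopifnot(n_rays >= 1)
  d <- resolve_destination(env, dest)
  if (d$width <= 0 || d$z1 <= d$z0)
    stop("degenerate (zero-area) destination surface")
  k <- max(1L, floor(sqrt(n_rays)))
  u <- (seq_len(k) - 0.5) / k
  ## door plane: tangent in plan is perpendicular to the outward normal
  tx <- -d$ny; ty <- d$nx
  gy <- rep(u, times = k); gz <- rep(u, each = k)
  px <- d$cx + (gy - 0.5) * d$width * tx
  py <- d$cy + (gy - 0.5) * d$width * ty
  pz <- d$z0 + gz * (d$z1 - d$z0)
  eye <- c(pose$x, pose$y, pose$z + eye_height)
  rx <- px - eye[1]; ry <- py - eye[2]; rz <- pz - eye[3]
  hor <- sqrt(rx^2 + ry^2)
  len <- sqrt(hor^2 + rz^2)
  az <- rad2deg(atan2(ry, rx))
  el <- rad2deg(atan2(rz, hor))
  ok <- abs(normalize_angle(az - pose$yaw)) <= fov$horizontal / 2 &
    abs(el - pose$pitch) <= fov$vertical / 2 &
    len <= fov$range &
    (rx * d$nx + ry * d$ny) < -1e-12        # front-face approach
  ok <- ok & !rays_blocked(eye, px, py, pz, env)
  structure(list(fraction_visible = sum(ok) / (k * k),
                 n_rays_cast = as.integer(k * k),
                 n_rays_reaching = as.integer(sum(ok))),
            class = "wv_visibility_sample")
}

resolve_destination <- function(env, dest) {
  if (is.character(dest)) {
    i <- match(dest, env$destinations$id)
    if (is.na(i)) stop("unknown destination id: ", dest)
    return(env$destinations[i, ])
  }
  dest
}

## Are eye->target segments intercepted by walls or the perforated slab?
## Vectorized over targets.
rays_blocked <- function(eye, px, py, pz, env) {
  blocked <- rep(FALSE, length(px))
  rx <- px - eye[1]; ry <- py - eye[2]; rz <- pz - eye[3]
  w <- env$walls[env$walls$occludes, , drop = FALSE]
  for (i in seq_len(nrow(w))) {
    ax <- w$x1[i]; ay <- w$y1[i]
    wx <- w$x2[i] - ax; wy <- w$y2[i] - ay
    den <- rx * wy - ry * wx
    t <- ((ax - eye[1]) * wy - (ay - eye[2]) * wx) / den
    s <- ((ax - eye[1]) * ry - (ay - eye[2]) * rx) / den
    z <- eye[3] + t * rz
    blocked <- blocked | (abs(den) > 1e-12 & t > 1e-9 & t < 1 - 1e-9 &
                            s >= -1e-9 & s <= 1 + 1e-9 &
                            z > w$z0[i] + 1e-9 & z < w$z1[i] - 1e-9)
  }
  ## second-floor slab with atrium holes
  sz <- env$slab$z
  cross <- (eye[3] - sz) * (pz - sz) < 0
  if (any(cross)) {
    t <- (sz - eye[3]) / rz[cross]
    qx <- eye[1] + t * rx[cross]
    qy <- eye[2] + t * ry[cross]
    inslab <- points_in_poly(qx, qy, env$slab$outer)
    for (h in env$slab$holes)
      inslab <- inslab & !points_in_poly(qx, qy, h)
    blocked[cross] <- blocked[cross] | inslab
  }
  blocked
}

#' Walkable cells visible from a pose through a field of view
#'
#' Same-floor cells whose centers fall inside the horizontal field-of-view
#' wedge and view range and have an unobstructed 2D line of sight at eye
#' height. This is the percept the agent uses to read the drift field.
#'
#' @param grid a \code{wv_navgrid}.
#' @param env a \code{wv_environment}.
#' @param floor floor number.
#' @param pose pose list (x, y, z, yaw).
#' @param fov a \code{wv_fov}.
#' @param eye_height eye height above the floor.
#' @return integer vector of visible walkable global cell indices.
#' @export
cells_in_fov <- function(grid, env, floor, pose, fov = agent_fov(),
                         eye_height = env$params$eye_height) {
  idx <- which(grid$cell_floor == floor & grid$walk)
  dx <- grid$cell_x[idx] - pose$x
  dy <- grid$cell_y[idx] - pose$y
  r <- sqrt(dx^2 + dy^2)
  az <- rad2deg(atan2(dy, dx))
  keep <- r <= fov$range &
    (r < 1e-9 | abs(normalize_angle(az - pose$yaw)) <= fov$horizontal / 2)
  idx <- idx[keep]; dx <- dx[keep]; dy <- dy[keep]
  if (!length(idx)) return(integer(0))
  eye_z <- env$floors[[floor]]$elevation + eye_height
  segs <- wall_segments(env, eye_z)
  vis <- rep(TRUE, length(idx))
  for (i in seq_len(nrow(segs))) {
    ax <- segs[i, 1]; ay <- segs[i, 2]
    wx <- segs[i, 3] - ax; wy <- segs[i, 4] - ay
    den <- dx * wy - dy * wx
    t <- ((ax - pose$x) * wy - (ay - pose$y) * wx) / den
    s <- ((ax - pose$x) * dy - (ay - pose$y) * dx) / den
    vis <- vis & !(abs(den) > 1e-12 & t > 1e-9 & t < 1 - 1e-9 &
                     s >= -1e-9 & s <= 1 + 1e-9)
  }
  idx[vis]
}

#' Export a drift field as a long CSV raster
#'
#' One row per walkable cell: floor, x, y, drift.
#'
#' @param field a \code{wv_drift_field}.
#' @param grid the matching \code{wv_navgrid}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_drift_csv <- function(field, grid, path) {
  i <- which(!is.na(field$drift))
  utils::write.csv(data.frame(floor = grid$cell_floor[i],
                              x = grid$cell_x[i], y = grid$cell_y[i],
                              drift = field$drift[i]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export one floor of a drift field as an ESRI ASCII grid
#'
#' @param field a \code{wv_drift_field}.
#' @param grid the matching \code{wv_navgrid}.
#' @param floor floor number.
#' @param path output file.
#' @param nodata value written for unwalkable cells.
#' @return the path, invisibly.
#' @export
write_drift_asc <- function(field, grid, floor, path, nodata = -9999) {
  fl <- grid$floors[[floor]]
  v <- field$drift[fl$offset + seq_len(fl$nx * fl$ny)]
  m <- matrix(v, fl$nx, fl$ny)
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", fl$nx), sprintf("nrows %d", fl$ny),
               sprintf("xllcorner %g", fl$x0), sprintf("yllcorner %g", fl$y0),
               sprintf("cellsize %g", fl$res),
               sprintf("NODATA_value %g", nodata)), con)
  for (iy in rev(seq_len(fl$ny)))
    writeLines(paste(format(m[, iy], trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' Export an isovist polygon as GeoJSON
#'
#' @param iso a \code{wv_isovist}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_isovist_geojson <- function(iso, path) {
  ring <- rbind(iso$polygon, iso$polygon[1, ])
  gj <- list(type = "Feature",
             properties = list(area = iso$area,
                               drift = isovist_drift(iso)),
             geometry = list(type = "Polygon",
                             coordinates = list(unname(
                               lapply(seq_len(nrow(ring)),
                                      function(i) as.numeric(ring[i, ]))))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
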