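## Planar geometry primitives used by the environment builder and the
## visibility engine. Polygons are n x 2 matrices of vertices, not closed
## (the first vertex is not repeated at the end).

#' Signed area of a simple polygon
#'
#' Shoelace formula; positive for counter-clockwise vertex order.
#'
#' @param poly numeric matrix with columns x, y.
#' @return signed area in square meters.
#' @export
poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Area centroid of a simple polygon
#'
#' @param poly numeric matrix with columns x, y.
#' @return numeric length-2 vector (x, y).
#' @export
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Test points against a simple polygon
#'
#' Ray-crossing test, vectorized over points. Points exactly on the boundary
#' may fall on either side; callers keep query points off polygon edges.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly polygon matrix.
#' @return logical vector.
#' @export
points_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Is a polygon convex?
#'
#' Collinear (zero-turn) vertices are allowed.
#'
#' @param poly polygon matrix.
#' @param tol cross-product tolerance.
#' @return logical scalar.
#' @export
is_convex <- function(poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  e <- poly[nxt, , drop = FALSE] - poly
  cr <- e[, 1] * e[nxt, 2] - e[, 2] * e[nxt, 1]
  all(cr >= -tol) || all(cr <= tol)
}

#' Axis-aligned rectangle as a polygon
#'
#' @param x0,y0,x1,y1 rectangle bounds.
#' @return 4 x 2 polygon matrix (counter-clockwise).
#' @export
rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Partition a rectilinear polygon into rectangles
#'
#' Vertical-slab decomposition: the polygon is sliced at every distinct vertex
#' x-coordinate and each slice is cut into the y-intervals covered by the
#' polygon, yielding an exact tiling by axis-aligned rectangles (all convex).
#' Only rectilinear (axis-aligned-edge) simple polygons are supported; this is
#' the shape family produced by the building generator.
#'
#' @param poly rectilinear polygon matrix.
#' @return list of rectangles, each \code{c(x0, y0, x1, y1)}.
#' @export
convex_partition <- function(poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  dx <- poly[nxt, 1] - poly[, 1]
  dy <- poly[nxt, 2] - poly[, 2]
  if (any(abs(dx) > 1e-9 & abs(dy) > 1e-9))
    stop("convex_partition() supports rectilinear polygons only")
  xs <- sort(unique(poly[, 1]))
  out <- list()
  ## horizontal edges only: each crossing of a vertical midline marks an
  ## in/out boundary of the interior
  hor <- which(abs(dy) < 1e-9 & abs(dx) > 1e-9)
  for (k in seq_len(length(xs) - 1)) {
    x0 <- xs[k]; x1 <- xs[k + 1]
    xm <- (x0 + x1) / 2
    ymins <- numeric(0)
    for (i in hor) {
      ex0 <- min(poly[i, 1], poly[nxt[i], 1])
      ex1 <- max(poly[i, 1], poly[nxt[i], 1])
      if (ex0 < xm && xm < ex1) ymins <- c(ymins, poly[i, 2])
    }
    ymins <- sort(ymins)
    if (length(ymins) %% 2 != 0)
      stop("degenerate rectilinear polygon")
    for (j in seq(1, length(ymins), by = 2)) {
      out[[length(out) + 1]] <- as.numeric(c(x0, ymins[j], x1,
                                             ymins[j + 1]))
    }
  }
  ## merge x-adjacent rectangles sharing an identical y-interval, so an
  ## obstacle-free rectangle comes back as a single piece
  merged <- TRUE
  while (merged) {
    merged <- FALSE
    for (i in seq_along(out)) {
      for (j in seq_along(out)) {
        if (i >= j) next
        a <- out[[i]]; b <- out[[j]]
        if (abs(a[2] - b[2]) < 1e-9 && abs(a[4] - b[4]) < 1e-9 &&
            (abs(a[3] - b[1]) < 1e-9 || abs(b[3] - a[1]) < 1e-9)) {
          out[[i]] <- c(min(a[1], b[1]), a[2], max(a[3], b[3]), a[4])
          out[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  out
}

#' Normalize an angle to [-180, 180)
#'
#' @param deg angle(s) in degrees.
#' @return normalized angle(s).
#' @export
normalize_angle <- function(deg) {
  ((deg + 180) %% 360) - 180
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

## Euclidean distance between 2D points (vectorized over the first argument)
dist2d <- function(px, py, qx, qy) sqrt((px - qx)^2 + (py - qy)^2)

## length of a polyline given as an n x k matrix of vertices
polyline_length <- function(m) {
  if (nrow(m) < 2) return(0)
  sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}
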