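#' Closed planar polygon for a probe cross-section contour
#'
#' Vertices are stored open (first vertex not repeated; closure is
#' implicit), in the section plane with x lateral and y the depth measured
#' positive downward from the probe's top surface, um. The polygon must be
#' simple (non-self-intersecting) and enclose positive area.
#'
#' @param vertices Two-column numeric matrix (or data.frame) of x, y in um.
#' @return An object of class `"section_polygon"`: a matrix with columns
#'   `x`, `y`.
#' @export
section_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("`vertices` must have two columns (x, y)")
  storage.mode(v) <- "double"
  if (any(!is.finite(v))) stop("polygon vertices must be finite")
  # drop an explicitly repeated closing vertex
  n <- nrow(v)
  if (n >= 2L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3L) stop("a polygon needs at least 3 distinct vertices")
  colnames(v) <- c("x", "y")
  if (.polygon_self_intersects(v))
    stop("polygon is self-intersecting; only simple polygons are supported")
  if (abs(.polygon_signed_area(v)) < .Machine$double.eps * 100)
    stop("polygon encloses (near-)zero area")
  structure(v, class = "section_polygon")
}

#' @export
print.section_polygon <- function(x, ...) {
  cat(sprintf("Section polygon: %d vertices, area %.6g um^2 (y positive = depth)\n",
              nrow(x), polygon_area(x)))
  invisible(x)
}

#' @export
as.data.frame.section_polygon <- function(x, ...) {
  data.frame(x = x[, 1L], y = x[, 2L])
}

.polygon_signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# O(n^2) proper-crossing check between non-adjacent edges; adequate for the
# small contours this package manipulates.
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  ax <- v[, 1L]; ay <- v[, 2L]
  bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    # edge n is adjacent to edge 1
    if (i == 1L) js <- js[js != n]
    if (!length(js)) next
    hit <- .segments_properly_cross(ax[i], ay[i], bx[i], by[i],
                                    ax[js], ay[js], bx[js], by[js])
    if (any(hit)) return(TRUE)
  }
  FALSE
}

# vectorised over the second segment set; strict straddle test on both
# supporting lines (shared endpoints / tangencies do not count)
.segments_properly_cross <- function(p0x, p0y, p1x, p1y, q0x, q0y, q1x, q1y) {
  d1 <- (p1x - p0x) * (q0y - p0y) - (p1y - p0y) * (q0x - p0x)
  d2 <- (p1x - p0x) * (q1y - p0y) - (p1y - p0y) * (q1x - p0x)
  d3 <- (q1x - q0x) * (p0y - q0y) - (q1y - q0y) * (p0x - q0x)
  d4 <- (q1x - q0x) * (p1y - q0y) - (q1y - q0y) * (p1x - q0x)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Polygon contour of a parametric cross-section
#'
#' Realizes a rectangle or T-beam as an explicit closed contour in the
#' section plane (x lateral, y depth-positive-down, origin at the top-left
#' corner of the planar portion). The T-beam contour is the outline of the
#' planar rectangle with the trapezoidal fin attached centred beneath it
#' (8 vertices).
#'
#' @param section A `rect_section` or `tbeam_section`.
#' @return A [section_polygon()].
#' @examples
#' make_contour(rect_section(65, 34))
#' make_contour(tbeam_section(65, 11, 27.5, 16, 2))
#' @export
make_contour <- function(section) UseMethod("make_contour")

#' @export
make_contour.rect_section <- function(section) {
  b <- section$width_b; h <- section$thickness_h
  section_polygon(rbind(c(0, 0), c(b, 0), c(b, h), c(0, h)))
}

#' @export
make_contour.tbeam_section <- function(section) {
  w <- section$planar_width; t <- section$planar_thickness
  d <- section$fin_depth
  wtop <- section$fin_top_width; wtip <- section$fin_tip_width
  cx <- w / 2
  ytip <- t + d
  if (wtip > 0) {
    v <- rbind(
      c(0, 0), c(w, 0), c(w, t),
      c(cx + wtop / 2, t),
      c(cx + wtip / 2, ytip),
      c(cx - wtip / 2, ytip),
      c(cx - wtop / 2, t),
      c(0, t))
  } else {
    # triangular fin: tip collapses to one vertex
    v <- rbind(
      c(0, 0), c(w, 0), c(w, t),
      c(cx + wtop / 2, t),
      c(cx, ytip),
      c(cx - wtop / 2, t),
      c(0, t))
  }
  # fin spanning the full planar width degenerates to a single tall outline
  if (wtop == w && wtip == w) {
    v <- rbind(c(0, 0), c(w, 0), c(w, ytip), c(0, ytip))
  }
  section_polygon(v)
}

#' Area enclosed by a polygon
#'
#' Shoelace formula; orientation-independent (absolute value), um^2.
#'
#' @param poly A [section_polygon()] or a two-column vertex matrix.
#' @return Area, um^2.
#' @export
polygon_area <- function(poly) {
  v <- .as_vertex_matrix(poly)
  abs(.polygon_signed_area(v))
}

#' Centroid of a polygon
#'
#' @inheritParams polygon_area
#' @return Numeric length-2 vector `c(x, y)`, um.
#' @export
polygon_centroid <- function(poly) {
  v <- .as_vertex_matrix(poly)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(x = sum((x + xn) * cr) / (6 * a),
    y = sum((y + yn) * cr) / (6 * a))
}

#' Second moment of area of a polygon about its centroidal horizontal axis
#'
#' Exact vertex-sum (shoelace-type) second-moment formula: the moment about
#' the x-axis through the origin, shifted to the centroid by the
#' parallel-axis theorem. Orientation- and translation-independent. Serves
#' as the independent oracle for the closed-form [second_moment()] of
#' parametric sections.
#'
#' @inheritParams polygon_area
#' @return I in um^4 about the horizontal axis through the polygon centroid.
#' @examples
#' polygon_second_moment(make_contour(rect_section(65, 34)))
#' @export
polygon_second_moment <- function(poly) {
  v <- .as_vertex_matrix(poly)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cy <- sum((y + yn) * cr) / (6 * a)
  ix0 <- sum((y^2 + y * yn + yn^2) * cr) / 12   # about y = 0, signed with a
  abs(ix0 - a * cy^2)                           # parallel-axis back to centroid
}

.as_vertex_matrix <- function(poly) {
  if (inherits(poly, "section_polygon")) return(unclass(poly))
  v <- as.matrix(poly)
  if (ncol(v) != 2L) stop("expected a two-column vertex matrix")
  n <- nrow(v)
  if (n >= 2L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (inherits(poly, "matrix") || is.data.frame(poly)) {
    if (.polygon_self_intersects(v))
      stop("polygon is self-intersecting; only simple polygons are supported")
  }
  v
}

#' Rigid-body placement of a polygon
#'
#' Rotates the polygon by `theta` (radians, counter-clockwise in the x/y
#' frame) about its own centroid, then translates the centroid to
#' `(x, y)`. Rotating about the centroid makes the placement distribution
#' independent of where the contour's vertex origin happens to sit.
#'
#' @param poly A [section_polygon()].
#' @param x,y Target centroid position, um.
#' @param theta Rotation angle, radians.
#' @return A `section_polygon` at the new pose.
#' @export
place_polygon <- function(poly, x, y, theta = 0) {
  v <- .as_vertex_matrix(poly)
  cen <- polygon_centroid(poly)
  dx <- v[, 1L] - cen[[1L]]
  dy <- v[, 2L] - cen[[2L]]
  ct <- cos(theta); st <- sin(theta)
  out <- cbind(x + ct * dx - st * dy,
               y + st * dx + ct * dy)
  colnames(out) <- c("x", "y")
  structure(out, class = "section_polygon")
}

#' Radius of the circle circumscribing a polygon about its centroid
#'
#' Used to shrink Monte Carlo placement regions so a rotated footprint
#' stays inside the sampling window at any angle.
#'
#' @inheritParams polygon_area
#' @return Radius, um.
#' @export
polygon_circumradius <- function(poly) {
  v <- .as_vertex_matrix(poly)
  cen <- polygon_centroid(poly)
  sqrt(max((v[, 1L] - cen[[1L]])^2 + (v[, 2L] - cen[[2L]])^2))
}

# Strict point-in-polygon (ray casting), vectorised over points. Points on
# the boundary are not guaranteed either way; the damage model treats
# boundary contact as measure-zero and never relies on it.
.points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (yn[i] > py))
    if (any(crosses)) {
      xint <- x[i] + (py[crosses] - y[i]) * (xn[i] - x[i]) / (yn[i] - y[i])
      flip <- px[crosses] < xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# Does each 2-D segment intersect the OPEN interior of polygon v?
# TRUE iff an endpoint is strictly inside, or the segment properly crosses a
# polygon edge. Tangency (touching with zero interior overlap) is FALSE.
# Vectorised over segments.
.segments_hit_polygon <- function(x0, y0, x1, y1, v) {
  hit <- .points_in_polygon(x0, y0, v) | .points_in_polygon(x1, y1, v)
  n <- nrow(v)
  ax <- v[, 1L]; ay <- v[, 2L]
  bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
  todo <- which(!hit)
  for (i in seq_len(n)) {
    if (!length(todo)) break
    cross <- .segments_properly_cross(ax[i], ay[i], bx[i], by[i],
                                      x0[todo], y0[todo], x1[todo], y1[todo])
    hit[todo[cross]] <- TRUE
    todo <- todo[!cross]
  }
  hit
}
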