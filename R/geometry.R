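## Pure 2-D geometric primitives underlying landmark and angle extraction.
## All functions work in pixel coordinates, image convention (y down).

.dot2 <- function(a, b) a[1L] * b[1L] + a[2L] * b[2L]
.norm2 <- function(a) sqrt(a[1L]^2 + a[2L]^2)
.unit2 <- function(a) a / .norm2(a)
.cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]
## clockwise perpendicular as seen on screen (y down): up -> right
.cwPerp <- function(d) c(-d[2L], d[1L])

## Tolerances (see the methods vignette for rationale)
.EPS_AREA <- 1e-9   # collinearity: triangle area < .EPS_AREA * span^2
.EPS_DIST <- 1e-6   # px; intersections closer than this to the segment start are dropped

#' Circumcircle of three points
#'
#' The unique circle through three non-collinear points, obtained by
#' solving the 2 x 2 perpendicular-bisector system. This is the head-fit
#' primitive: the femoral head centre is taken as the centre of the circle
#' through three well-spread points on the head contour.
#'
#' @param p1,p2,p3 numeric length-2 points, pairwise distinct.
#' @return A [Circle-class].
#' @section Errors: a degenerate-geometry error if the points are
#'   collinear (triangle area below `1e-9 * span^2`, `span` = largest
#'   pairwise distance) or not pairwise distinct.
#' @examples
#' circumcircle(c(0, 1), c(1, 0), c(-1, 0))  # unit circle at the origin
#' @export
circumcircle <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  span <- max(.norm2(p2 - p1), .norm2(p3 - p1), .norm2(p3 - p2))
  if (span == 0) degenerateGeometryError("points are not pairwise distinct")
  area <- abs(.cross2(p2 - p1, p3 - p1)) / 2
  if (area < .EPS_AREA * span^2)
    degenerateGeometryError("points are collinear (or nearly so); no unique circumcircle")
  A <- rbind(p2 - p1, p3 - p1)
  b <- c(.dot2(p2 - p1, (p1 + p2) / 2), .dot2(p3 - p1, (p1 + p3) / 2))
  ctr <- as.numeric(solve(A, b))
  new("Circle", center = ctr, radius = .norm2(p1 - ctr))
}

#' Build the pelvic frame from the two teardrop points
#'
#' Connects the inferior edges of the two teardrops into the pelvic
#' horizontal axis (line a) and returns the orthonormal frame used by all
#' angle definitions. By default anatomical sides are inferred from image
#' x-order (a standard AP radiograph shows the patient's left hip on the
#' image right, i.e. at larger x), which makes the result invariant under
#' swapping the two arguments. Pass `sides` to override — required for
#' images rotated by 45 degrees or more, where x-order is no longer
#' diagnostic.
#'
#' @param t1,t2 the two teardrop inferior points (any order when `sides`
#'   is `NULL`).
#' @param sides `NULL`, or a character vector of length 2 giving the
#'   anatomical side (`"left"`/`"right"`) of `t1` and `t2` respectively.
#' @return A [PelvisFrame-class].
#' @section Errors: degenerate-geometry error on coincident teardrops.
#' @examples
#' buildFrame(c(80, 120), c(220, 121))
#' @export
buildFrame <- function(t1, t2, sides = NULL) {
  t1 <- as.numeric(t1); t2 <- as.numeric(t2)
  if (all(t1 == t2))
    degenerateGeometryError("teardrop points coincide; cannot build line a")
  if (is.null(sides)) {
    if (t1[1L] == t2[1L])
      degenerateGeometryError(
        "teardrops share the same x; cannot infer anatomical sides (pass 'sides')")
    sides <- if (t1[1L] > t2[1L]) c("left", "right") else c("right", "left")
  }
  if (length(sides) != 2L || !setequal(sides, .SIDES))
    inputError("'sides' must assign one 'left' and one 'right'")
  tl <- if (sides[1L] == "left") t1 else t2
  tr <- if (sides[1L] == "right") t1 else t2
  d <- .unit2(tl - tr)
  new("PelvisFrame", teardropLeft = tl, teardropRight = tr,
    axisUnit = d, superiorUnit = c(d[2L], -d[1L]))
}

#' Per-side unit vectors of a pelvic frame
#'
#' `lateralUnit()` points along line a away from the pelvic midline for
#' the given hip; `frameTeardrop()` returns that side's teardrop point.
#'
#' @param frame a [PelvisFrame-class].
#' @param side `"left"` or `"right"` (anatomical).
#' @return A unit numeric length-2 vector / a point.
#' @export
lateralUnit <- function(frame, side) {
  side <- match.arg(side, .SIDES)
  if (side == "left") frame@axisUnit else -frame@axisUnit
}

#' @rdname lateralUnit
#' @export
frameTeardrop <- function(frame, side) {
  side <- match.arg(side, .SIDES)
  if (side == "left") frame@teardropLeft else frame@teardropRight
}

#' Extremal vertex of a polyline along a direction
#'
#' Returns the trace vertex with the largest scalar projection onto
#' `direction`. Ties (projections within `1e-9 * span` of the maximum) are
#' broken deterministically by the larger projection onto the clockwise
#' perpendicular of `direction`.
#'
#' @param trace a [ContourTrace-class] (or a bare n x 2 matrix).
#' @param direction numeric length-2 vector (need not be unit length).
#' @return A numeric length-2 point (a vertex of the trace).
#' @export
extremalPoint <- function(trace, direction) {
  pts <- if (is(trace, "ContourTrace")) trace@points else as.matrix(trace)
  direction <- as.numeric(direction)
  if (.norm2(direction) == 0) degenerateGeometryError("direction must be nonzero")
  pr <- as.numeric(pts %*% direction)
  tol <- 1e-9 * max(diff(range(pr)), 1)
  cand <- which(pr >= max(pr) - tol)
  if (length(cand) > 1L) {
    pr2 <- as.numeric(pts[cand, , drop = FALSE] %*% .cwPerp(direction))
    cand <- cand[which.max(pr2)]
  }
  as.numeric(pts[cand[1L], ])
}

#' Intersections of a segment with a polyline
#'
#' All intersection points of the closed segment `[a, b]` with the
#' polyline, ordered by increasing distance from `a`. Intersections within
#' `1e-6` px of `a` are dropped (guard against trivially re-finding the
#' start point when `a` itself lies on the polyline); duplicates arising
#' from shared polyline vertices are merged. Polyline edges parallel to
#' the segment contribute no intersection points.
#'
#' @param a,b segment endpoints, `a != b`.
#' @param trace a [ContourTrace-class] or n x 2 matrix.
#' @return A matrix with columns x, y (possibly 0 rows).
#' @export
segmentPolylineIntersections <- function(a, b, trace) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (all(a == b)) inputError("segment endpoints must differ")
  pts <- if (is(trace, "ContourTrace")) trace@points else as.matrix(trace)
  d1 <- b - a
  scale <- max(.norm2(d1), 1)
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(pts) - 1L)) {
    p <- as.numeric(pts[i, ])
    d2 <- as.numeric(pts[i + 1L, ]) - p
    det <- .cross2(d1, -d2)
    if (abs(det) < 1e-14 * scale * max(.norm2(d2), 1)) next
    rhs <- p - a
    t <- .cross2(rhs, -d2) / det
    u <- .cross2(d1, rhs) / det
    if (t >= 0 && t <= 1 && u >= 0 && u <= 1)
      out <- rbind(out, a + t * d1)
  }
  if (nrow(out) == 0L) {
    colnames(out) <- c("x", "y")
    return(out)
  }
  dist <- sqrt(rowSums((out - matrix(a, nrow(out), 2L, byrow = TRUE))^2))
  keep <- dist > .EPS_DIST
  out <- out[keep, , drop = FALSE]; dist <- dist[keep]
  o <- order(dist)
  out <- out[o, , drop = FALSE]; dist <- dist[o]
  if (nrow(out) > 1L) {
    dup <- c(FALSE, diff(dist) < .EPS_DIST &
      sqrt(rowSums(diff(out)^2)) < .EPS_DIST)
    out <- out[!dup, , drop = FALSE]
  }
  colnames(out) <- c("x", "y")
  out
}

#' Vertex angle between two vectors
#'
#' The unsigned angle in degrees, `acos` of the normalised dot product
#' clamped to `[-1, 1]`; range `[0, 180]`.
#'
#' @param u,v nonzero numeric length-2 vectors.
#' @return degrees.
#' @examples
#' vertexAngle(c(1, 0), c(0, 1))  # 90
#' vertexAngle(c(3, -4), c(1, 0)) # 53.130
#' @export
vertexAngle <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  nu <- .norm2(u); nv <- .norm2(v)
  if (nu == 0 || nv == 0) degenerateGeometryError("vectors must be nonzero")
  acos(max(-1, min(1, .dot2(u, v) / (nu * nv)))) * 180 / pi
}

#' Rotate points about a centre
#'
#' Utility for equivariance checks and phantom construction. Rotation is
#' by `degrees` counter-clockwise on screen (image convention, y down).
#'
#' @param pts an n x 2 matrix or a length-2 point.
#' @param degrees rotation angle.
#' @param center pivot point.
#' @return Same shape as `pts`.
#' @export
rotatePoints <- function(pts, degrees, center = c(0, 0)) {
  th <- degrees * pi / 180
  ## y-down screen CCW corresponds to a clockwise rotation in math axes
  R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  vec <- is.null(dim(pts))
  m <- if (vec) matrix(as.numeric(pts), 1L) else as.matrix(pts)
  ctr <- matrix(as.numeric(center), nrow(m), 2L, byrow = TRUE)
  out <- (m - ctr) %*% t(R) + ctr
  if (vec) as.numeric(out) else {colnames(out) <- c("x", "y"); out}
}
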