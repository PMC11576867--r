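## Planar polygon primitives shared by the morphometry and generator code.
## Polygons are n x 2 matrices of vertices in micrometres, implicitly closed
## (the terminal vertex is NOT repeated), counter-clockwise after load.

#' Signed polygon area (shoelace formula)
#'
#' @param v numeric matrix with two columns (x, y); implicitly closed.
#' @return Signed area; positive for counter-clockwise vertex order.
#' @keywords internal
polygonSignedArea <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

#' @keywords internal
polygonPerimeter <- function(v) {
  dx <- diff(c(v[, 1L], v[1L, 1L]))
  dy <- diff(c(v[, 2L], v[1L, 2L]))
  sum(sqrt(dx^2 + dy^2))
}

#' Area centroid of a simple polygon
#' @keywords internal
polygonCentroid <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(v))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

#' Convex hull vertices in traversal order
#' @keywords internal
convexHullPts <- function(v) {
  v[grDevices::chull(v[, 1L], v[, 2L]), , drop = FALSE]
}

#' Test whether points fall inside a polygon
#'
#' Thin wrapper over [mgcv::in.out()] with the boundary ring closed.
#'
#' @param pts n x 2 matrix of query points.
#' @param poly m x 2 polygon vertex matrix (open ring).
#' @return Logical vector, `TRUE` for points inside.
#' @keywords internal
pointsInPolygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  bnd <- rbind(poly, poly[1L, ])
  mgcv::in.out(bnd, pts)
}

#' Minimum distance from points to a polygon boundary
#' @keywords internal
distanceToBoundary <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  a <- poly
  b <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE])
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  len2 <- ex^2 + ey^2
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    px <- pts[i, 1L] - a[, 1L]; py <- pts[i, 2L] - a[, 2L]
    t <- pmin(pmax((px * ex + py * ey) / len2, 0), 1)
    dx <- px - t * ex; dy <- py - t * ey
    out[i] <- sqrt(min(dx^2 + dy^2))
  }
  out
}

## Orientation of triplet (a, b, c): sign of the cross product.
.orient <- function(ax, ay, bx, by, cx, cy) {
  sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
}

#' Detect self-intersection of a closed polygon
#'
#' Proper or improper crossing between any two non-adjacent edges. O(n^2)
#' pairwise test, chunked to bound memory for high-resolution contours.
#'
#' @param v polygon vertex matrix (open ring).
#' @return `TRUE` if any two non-adjacent edges intersect.
#' @keywords internal
polygonSelfIntersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  a <- v
  b <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  idx <- seq_len(n)
  chunk <- max(1L, 2000000L %/% n)
  for (start in seq(1L, n, by = chunk)) {
    ii <- start:min(start + chunk - 1L, n)
    ## pair every edge i in chunk with every edge j > i + 1 (mod wrap)
    pi <- rep(ii, each = n)
    pj <- rep(idx, times = length(ii))
    keep <- pj > pi + 1L & !(pi == 1L & pj == n)
    if (!any(keep)) next
    pi <- pi[keep]; pj <- pj[keep]
    p1x <- a[pi, 1L]; p1y <- a[pi, 2L]; p2x <- b[pi, 1L]; p2y <- b[pi, 2L]
    q1x <- a[pj, 1L]; q1y <- a[pj, 2L]; q2x <- b[pj, 1L]; q2y <- b[pj, 2L]
    d1 <- .orient(p1x, p1y, p2x, p2y, q1x, q1y)
    d2 <- .orient(p1x, p1y, p2x, p2y, q2x, q2y)
    d3 <- .orient(q1x, q1y, q2x, q2y, p1x, p1y)
    d4 <- .orient(q1x, q1y, q2x, q2y, p2x, p2y)
    cross <- d1 * d2 < 0 & d3 * d4 < 0
    if (any(cross)) return(TRUE)
    ## collinear touching/overlap counts as intersection too
    col <- (d1 == 0 & .onSegment(p1x, p1y, p2x, p2y, q1x, q1y)) |
           (d2 == 0 & .onSegment(p1x, p1y, p2x, p2y, q2x, q2y)) |
           (d3 == 0 & .onSegment(q1x, q1y, q2x, q2y, p1x, p1y)) |
           (d4 == 0 & .onSegment(q1x, q1y, q2x, q2y, p2x, p2y))
    if (any(col)) return(TRUE)
  }
  FALSE
}

.onSegment <- function(ax, ay, bx, by, px, py) {
  px >= pmin(ax, bx) & px <= pmax(ax, bx) &
  py >= pmin(ay, by) & py <= pmax(ay, by)
}

#' Do two convex-ish polygons overlap?
#'
#' True if any vertex of one lies strictly inside the other or any pair of
#' edges crosses. Adequate for the fascicle-disjointness validator.
#' @keywords internal
polygonsOverlap <- function(va, vb) {
  if (any(pointsInPolygon(va, vb)) || any(pointsInPolygon(vb, va))) return(TRUE)
  ## edge crossing check between the two rings
  a1 <- va; a2 <- rbind(va[-1L, , drop = FALSE], va[1L, , drop = FALSE])
  b1 <- vb; b2 <- rbind(vb[-1L, , drop = FALSE], vb[1L, , drop = FALSE])
  na <- nrow(va); nb <- nrow(vb)
  pi <- rep(seq_len(na), each = nb); pj <- rep(seq_len(nb), times = na)
  d1 <- .orient(a1[pi, 1], a1[pi, 2], a2[pi, 1], a2[pi, 2], b1[pj, 1], b1[pj, 2])
  d2 <- .orient(a1[pi, 1], a1[pi, 2], a2[pi, 1], a2[pi, 2], b2[pj, 1], b2[pj, 2])
  d3 <- .orient(b1[pj, 1], b1[pj, 2], b2[pj, 1], b2[pj, 2], a1[pi, 1], a1[pi, 2])
  d4 <- .orient(b1[pj, 1], b1[pj, 2], b2[pj, 1], b2[pj, 2], a2[pi, 1], a2[pi, 2])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Vertices of a regular polygon approximating a circle
#'
#' @param n number of vertices.
#' @param r circumradius.
#' @param center length-2 numeric.
#' @param phase rotation offset in radians.
#' @return n x 2 vertex matrix, counter-clockwise.
#' @export
#' @examples
#' v <- regularPolygon(64, r = 5)
#' contourMeasures(v)
regularPolygon <- function(n, r = 1, center = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

#' Vertices of an ellipse polygon
#'
#' @param n number of vertices.
#' @param a,b semi-major and semi-minor axes.
#' @param center length-2 numeric.
#' @param angle rotation of the major axis, radians.
#' @return n x 2 vertex matrix, counter-clockwise.
#' @export
ellipsePolygon <- function(n, a, b, center = c(0, 0), angle = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  x <- a * cos(th); y <- b * sin(th)
  ca <- cos(angle); sa <- sin(angle)
  cbind(center[1L] + x * ca - y * sa, center[2L] + x * sa + y * ca)
}
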