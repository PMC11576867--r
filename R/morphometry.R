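## Geometric morphometry: areas, perimeters, Feret diameters, circularity
## metrics, shape-adjusted-ellipse (SAE) diameter correction, fiber and
## fascicle summaries, and size-distribution/modality analysis.

.contourVertices <- function(x) {
  if (methods::is(x, "Contour")) x@vertices else as.matrix(x)
}

#' Area and perimeter of a contour
#'
#' Area by the shoelace formula on the vertex polygon (returned positive);
#' perimeter as the sum of edge lengths including the closing edge. Raw
#' polygon vertices are used throughout — no smoothing is applied, so results
#' are deterministic functions of the segmentation.
#'
#' @param x a [`Contour-class`] or an n x 2 vertex matrix.
#' @return Named numeric vector `c(area, perimeter)` in micrometre units.
#' @export
#' @examples
#' contourMeasures(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # unit square
contourMeasures <- function(x) {
  v <- .contourVertices(x)
  if (nrow(v) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  a <- abs(polygonSignedArea(v))
  if (a <= 0) stop("degenerate polygon: zero area")
  c(area = a, perimeter = polygonPerimeter(v))
}

#' Minimum and maximum Feret (caliper) diameters
#'
#' Computed on the convex hull: the maximum Feret diameter is the largest
#' vertex-pair distance; the minimum Feret diameter is the smallest caliper
#' width over hull edge directions (rotating calipers).
#'
#' @param x a [`Contour-class`] or vertex matrix.
#' @return Named numeric vector `c(minFeret, maxFeret)`.
#' @export
#' @examples
#' feretDiameters(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)))  # c(1, sqrt(5))
feretDiameters <- function(x) {
  v <- .contourVertices(x)
  h <- convexHullPts(v)
  if (nrow(h) < 3L) stop("degenerate polygon: collinear vertices")
  ## max Feret: brute-force pairwise distances on hull vertices
  d2 <- as.matrix(stats::dist(h))
  maxF <- max(d2)
  ## min Feret: width orthogonal to each hull edge
  nh <- nrow(h)
  nxt <- c(seq_len(nh)[-1L], 1L)
  ex <- h[nxt, 1L] - h[, 1L]; ey <- h[nxt, 2L] - h[, 2L]
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  nxv <- -ey[keep] / len[keep]; nyv <- ex[keep] / len[keep]
  ## projections of all hull vertices onto each edge normal
  proj <- nxv %o% h[, 1L] + nyv %o% h[, 2L]
  widths <- apply(proj, 1L, function(p) diff(range(p)))
  c(minFeret = min(widths), maxFeret = maxF)
}

#' The five circularity metrics of a contour
#'
#' Shape factor `P / sqrt(A)`, form factor `4 pi A / P^2`, aspect ratio
#' `MinFeret / MaxFeret`, compactness `sqrt((4 / pi) A) / MaxFeret` and
#' roundness `4 A / (pi MaxFeret^2)`. A circle scores `2 sqrt(pi) ~ 3.54` on
#' the shape factor and 1 on the other four; `roundness == compactness^2` and
#' `formFactor * shapeFactor^2 == 4 pi` identically.
#'
#' @param x a [`Contour-class`] or vertex matrix.
#' @return One-row data.frame with columns area, perimeter, minFeret,
#'   maxFeret, shapeFactor, formFactor, aspectRatio, compactness, roundness.
#' @export
#' @examples
#' round(shapeMetrics(regularPolygon(4096))$shapeFactor, 2)  # 3.54
shapeMetrics <- function(x) {
  m <- contourMeasures(x)
  f <- feretDiameters(x)
  A <- m[["area"]]; P <- m[["perimeter"]]
  data.frame(
    area = A, perimeter = P,
    minFeret = f[["minFeret"]], maxFeret = f[["maxFeret"]],
    shapeFactor = P / sqrt(A),
    formFactor = 4 * pi * A / P^2,
    aspectRatio = f[["minFeret"]] / f[["maxFeret"]],
    compactness = sqrt(4 / pi * A) / f[["maxFeret"]],
    roundness = 4 * A / (pi * f[["maxFeret"]]^2))
}

#' Perimeter of an ellipse
#'
#' Ramanujan's second approximation (relative error below 1e-5 at every
#' eccentricity), or the exact complete-elliptic-integral value.
#'
#' @param a,b semi-axes (any order).
#' @param method "ramanujan" (default) or "exact".
#' @return Perimeter, same units as the axes.
#' @export
#' @examples
#' ellipsePerimeter(2, 1)
ellipsePerimeter <- function(a, b, method = c("ramanujan", "exact")) {
  method <- match.arg(method)
  if (method == "exact") {
    aa <- pmax(a, b); bb <- pmin(a, b)
    m <- 1 - (bb / aa)^2
    return(4 * aa * pracma::ellipke(m)$e)
  }
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Shape-adjusted-ellipse (SAE) corrected diameter
#'
#' Models an obliquely sectioned fiber as the ellipse whose cross-sectional
#' area and perimeter match the measured contour, and returns its minor
#' diameter `2 b`. With the aspect ratio `t = b / a` as unknown, the ellipse
#' perimeter at fixed area is strictly decreasing in `t`, so the inversion is
#' solved by monotone bracketing on `t` to a perimeter residual
#' `|dP| / P <= 1e-10`.
#'
#' A perimeter more than a relative 1e-6 below the equal-area circle bound
#' `2 sqrt(pi A)` is geometrically infeasible and raises an error; a
#' perimeter within that tolerance below the bound (digitization noise) is
#' clamped to the circle, returning `2 sqrt(A / pi)`.
#'
#' @param area cross-sectional area, square micrometres.
#' @param perimeter contour perimeter, micrometres.
#' @param method ellipse perimeter model, see [ellipsePerimeter()].
#' @return Minor diameter in micrometres (vectorized over inputs).
#' @export
#' @examples
#' saeDiameter(pi, 2 * pi)                    # circle of diameter 2
#' saeDiameter(2 * pi, ellipsePerimeter(2, 1))  # ellipse minor diameter 2
saeDiameter <- function(area, perimeter, method = c("ramanujan", "exact")) {
  method <- match.arg(method)
  if (length(area) != length(perimeter))
    stop("area and perimeter must have equal length")
  mapply(function(A, P) {
    if (!is.finite(A) || A <= 0) stop("area must be positive")
    Pcirc <- 2 * sqrt(pi * A)
    if (P < Pcirc * (1 - 1e-6))
      stop(sprintf(
        "infeasible contour: perimeter %.6g below the equal-area circle bound %.6g",
        P, Pcirc))
    if (P <= Pcirc) return(2 * sqrt(A / pi))
    resid <- function(t) {
      a <- sqrt(A / (pi * t)); b <- a * t
      ellipsePerimeter(a, b, method) - P
    }
    tlo <- 1e-8
    while (resid(tlo) < 0 && tlo > 1e-14) tlo <- tlo / 10
    r <- stats::uniroot(resid, c(tlo, 1), tol = .Machine$double.eps^0.75,
                        maxiter = 2000L)
    t <- r$root
    ## polish by bisection until the perimeter residual meets contract
    lo <- max(tlo, t * 0.99); hi <- min(1, t * 1.01)
    if (resid(lo) < 0) lo <- tlo
    if (resid(hi) > 0) hi <- 1
    for (i in 1:200) {
      if (abs(resid(t)) / P <= 1e-10) break
      mid <- (lo + hi) / 2
      if (resid(mid) > 0) lo <- mid else hi <- mid
      t <- (lo + hi) / 2
    }
    2 * sqrt(A * t / pi)
  }, area, perimeter)
}

#' Morphometry of a myelinated fiber
#'
#' SAE-corrected diameters of the myelin outer and inner contours, the
#' myelin thickness `(fiber - axon) / 2`, and the G-ratio `axon / fiber`.
#'
#' @param f a [`MyelinatedFiber-class`], or a myelin-outer
#'   [`Contour-class`] when `inner` is supplied.
#' @param inner optional myelin-inner [`Contour-class`].
#' @return Named numeric vector (fiberDiameter, axonDiameter,
#'   myelinThickness, gRatio).
#' @export
fiberMorphometry <- function(f, inner = NULL) {
  if (!methods::is(f, "MyelinatedFiber")) f <- MyelinatedFiber(f, inner)
  c(fiberDiameter = f@fiberDiameter, axonDiameter = f@axonDiameter,
    myelinThickness = f@myelinThickness, gRatio = f@gRatio)
}

#' All fibers of a fascicle, including those inside its sub-fascicles
#'
#' @param fa a [`Fascicle-class`].
#' @return List with elements `myelinated` and `unmyelinated`.
#' @export
allFibers <- function(fa) {
  my <- fa@myelinated
  um <- fa@unmyelinated
  for (s in fa@subfascicles) {
    sub <- allFibers(s)
    my <- c(my, sub$myelinated)
    um <- c(um, sub$unmyelinated)
  }
  list(myelinated = my, unmyelinated = um)
}

#' Fascicle-level morphometric summary
#'
#' Fascicle area (outer perineurium polygon), endoneurium area (inner
#' polygon), their difference (perineurium area), the outer circumference,
#' the endoneurium/fascicle area ratio, the five circularity metrics of the
#' outer contour, fiber counts (sub-fascicles included) and a sub-fascicle
#' flag.
#'
#' @param fa a [`Fascicle-class`].
#' @return One-row data.frame.
#' @export
fascicleSummary <- function(fa) {
  mo <- contourMeasures(fa@outer)
  mi <- contourMeasures(fa@inner)
  sm <- shapeMetrics(fa@outer)
  fib <- allFibers(fa)
  data.frame(
    fascicleId = fa@id,
    fascicleArea = mo[["area"]],
    endoneuriumArea = mi[["area"]],
    perineuriumArea = mo[["area"]] - mi[["area"]],
    circumference = mo[["perimeter"]],
    endoFascicleRatio = mi[["area"]] / mo[["area"]],
    shapeFactor = sm$shapeFactor, formFactor = sm$formFactor,
    aspectRatio = sm$aspectRatio, compactness = sm$compactness,
    roundness = sm$roundness,
    nMyelinated = length(fib$myelinated),
    nUnmyelinated = length(fib$unmyelinated),
    hasSubfascicles = length(fa@subfascicles) > 0L,
    stringsAsFactors = FALSE)
}

#' Fiber size distribution with modality summary
#'
#' Histogram with right-open bins of fixed width starting at zero, plus a
#' modality count: the number of local maxima of the 3-bin moving average of
#' the counts (zero-padded at the ends; plateaus collapse to one maximum).
#'
#' @param diameters numeric vector of diameters, micrometres.
#' @param binWidth bin width, micrometres.
#' @return Object of class `SizeDistribution`: list with `breaks`, `counts`,
#'   `mids`, `modality` and `peaks` (bin centers of the local maxima).
#' @export
#' @examples
#' sd1 <- sizeDistribution(c(1, 1, 1), 0.5)
#' sd1$modality  # 1
sizeDistribution <- function(diameters, binWidth) {
  if (!length(diameters)) stop("empty diameter vector")
  if (!is.finite(binWidth) || binWidth <= 0) stop("binWidth must be > 0")
  if (any(diameters < 0)) stop("diameters must be non-negative")
  nb <- max(1L, as.integer(ceiling(max(diameters) / binWidth + 1e-12)))
  breaks <- seq(0, by = binWidth, length.out = nb + 1L)
  idx <- pmin(as.integer(floor(diameters / binWidth)) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  padded <- c(0, counts, 0)
  sm <- (padded[seq_len(nb)] + padded[seq_len(nb) + 1L] +
         padded[seq_len(nb) + 2L]) / 3
  ## collapse equal-value plateaus, then count strict local maxima
  r <- rle(sm)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(vals)
  isMax <- logical(k)
  for (i in seq_len(k)) {
    leftOk <- i == 1L || vals[i] > vals[i - 1L]
    rightOk <- i == k || vals[i] > vals[i + 1L]
    isMax[i] <- leftOk && rightOk && vals[i] > 0
  }
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  peakBins <- vapply(which(isMax), function(i) {
    run <- starts[i]:ends[i]
    run[which.max(counts[run])]
  }, integer(1L))
  structure(list(breaks = breaks, counts = counts, mids = mids,
                 modality = sum(isMax), peaks = mids[peakBins]),
            class = "SizeDistribution")
}

#' @export
print.SizeDistribution <- function(x, ...) {
  cat(sprintf("SizeDistribution: %d fibers in %d bins of width %g um; %s (%d mode(s) at %s um)\n",
              sum(x$counts), length(x$counts), diff(x$breaks[1:2]),
              if (x$modality <= 1) "unimodal" else "multi-modal",
              x$modality, paste(signif(x$peaks, 3), collapse = ", ")))
  invisible(x)
}

#' Fraction of fascicles containing sub-fascicles
#'
#' @param x logical vector of per-fascicle sub-fascicle flags, or a
#'   data.frame with a `hasSubfascicles` column (e.g. rows of
#'   [fascicleSummary()]).
#' @return List with `count`, `total` and `percent` (0-100 scale).
#' @export
#' @examples
#' subfascicleFraction(rep(c(TRUE, FALSE), c(49, 268)))$percent  # 15.5
subfascicleFraction <- function(x) {
  if (is.data.frame(x)) x <- x$hasSubfascicles
  x <- as.logical(x)
  if (!length(x)) stop("no fascicles supplied")
  list(count = sum(x), total = length(x), percent = 100 * mean(x))
}
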