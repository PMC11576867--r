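test_that("contour measures match closed forms and a triangulation oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(unname(contourMeasures(sq)), c(1, 4))

  circ <- regularPolygon(4096)
  m <- contourMeasures(circ)
  expect_equal(m[["area"]], pi, tolerance = 1e-5)
  expect_equal(m[["perimeter"]], 2 * pi, tolerance = 1e-5)

  # independent oracle: fan triangulation from the origin of a star polygon
  set.seed(42)
  for (i in 1:20) {
    v <- randomStarPolygon(17L)
    nxt <- rbind(v[-1, ], v[1, ])
    fan <- sum(abs(v[, 1] * nxt[, 2] - nxt[, 1] * v[, 2]) / 2)
    expect_equal(contourMeasures(v)[["area"]], fan, tolerance = 1e-9)
  }

  degen <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_error(contourMeasures(degen), "degenerate")
})

test_that("Feret diameters agree with closed forms and an angle-sweep oracle", {
  rect <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))
  f <- feretDiameters(rect)
  expect_equal(unname(f), c(1, sqrt(5)), tolerance = 1e-12)

  f2 <- feretDiameters(regularPolygon(4096))
  expect_equal(unname(f2), c(2, 2), tolerance = 1e-4)

  # brute-force projection widths over 3600 angles on random convex
  # polygons, with two local refinement passes (the width function has a
  # kink at its minimizer, so the coarse sweep alone is only ~1e-4 accurate)
  width <- function(hull, a) {
    p <- hull[, 1] %o% cos(a) + hull[, 2] %o% sin(a)
    apply(p, 2, function(z) diff(range(z)))
  }
  sweepMin <- function(hull, fun) {
    th <- pi * (0:3599) / 3600
    for (pass in 1:3) {
      w <- width(hull, th)
      i <- if (identical(fun, min)) which.min(w) else which.max(w)
      best <- th[i]
      span <- diff(th[1:2])
      th <- seq(best - span, best + span, length.out = 2001)
    }
    fun(w)
  }
  set.seed(7)
  for (i in 1:10) {
    pts <- matrix(runif(40, -1, 1), ncol = 2)
    hull <- pts[chull(pts), ]
    f <- feretDiameters(hull)
    expect_equal(f[["minFeret"]], sweepMin(hull, min), tolerance = 1e-6)
    expect_equal(f[["maxFeret"]], sweepMin(hull, max), tolerance = 1e-6)
  }
})

test_that("circularity metrics: circle values, square values, identities", {
  sm <- shapeMetrics(regularPolygon(4096))
  expect_equal(round(sm$shapeFactor, 2), 3.54)
  expect_equal(round(c(sm$formFactor, sm$aspectRatio, sm$compactness,
                       sm$roundness), 2), rep(1, 4))

  # unit square: MinFeret is the side, MaxFeret the diagonal
  sq <- shapeMetrics(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(sq$shapeFactor, 4)
  expect_equal(sq$formFactor, pi / 4)
  expect_equal(sq$aspectRatio, 1 / sqrt(2))
  expect_equal(sq$roundness, 2 / pi)

  set.seed(11)
  for (i in 1:1000) {
    sm <- shapeMetrics(randomStarPolygon(12L))
    expect_equal(sm$roundness, sm$compactness^2, tolerance = 1e-9)
    expect_equal(sm$formFactor * sm$shapeFactor^2, 4 * pi,
                 tolerance = 1e-6)
    # isoperimetric extremality of the circle
    expect_lte(sm$formFactor, 1)
    expect_gte(sm$shapeFactor, 2 * sqrt(pi) - 1e-6)
  }
})

test_that("SAE diameter inverts the forward ellipse construction", {
  expect_equal(saeDiameter(pi, 2 * pi), 2)
  # forward-compute the perimeter with the same approximation, then invert
  expect_equal(saeDiameter(2 * pi, ramanujanPerimeter(2, 1)), 2,
               tolerance = 1e-9)
  expect_error(saeDiameter(1, 0.1), "infeasible")
  # sub-circular perimeter within tolerance clamps to the equal-area circle
  A <- pi
  expect_equal(saeDiameter(A, 2 * sqrt(pi * A) * (1 - 5e-7)), 2,
               tolerance = 1e-9)

  set.seed(5)
  for (i in 1:1000) {
    a <- runif(1, 0.2, 20)
    b <- a * runif(1, 0.05, 1)
    d <- saeDiameter(pi * a * b, ramanujanPerimeter(a, b))
    expect_equal(d, 2 * b, tolerance = 1e-8)
  }
})

test_that("exact elliptic-integral backend agrees with Ramanujan to its error", {
  a <- 3; b <- 0.9
  expect_equal(ellipsePerimeter(a, b, "exact"),
               ellipsePerimeter(a, b, "ramanujan"), tolerance = 1e-5)
  d <- saeDiameter(pi * a * b, ellipsePerimeter(a, b, "exact"),
                   method = "exact")
  expect_equal(d, 2 * b, tolerance = 1e-8)
})

test_that("fiber morphometry: thickness, G-ratio and range invariant", {
  # concentric circles of diameter 10 and 7 um
  out <- Contour(regularPolygon(4096, 5), "myelin_outer", "f:out")
  inn <- Contour(regularPolygon(4096, 3.5), "myelin_inner", "f:in", "f:out")
  fm <- fiberMorphometry(out, inn)
  expect_equal(fm[["gRatio"]], 0.7, tolerance = 1e-9)
  expect_equal(fm[["myelinThickness"]], 1.5, tolerance = 1e-2)
  expect_equal(fm[["fiberDiameter"]], 10, tolerance = 1e-2)

  # confocal ellipses (5,4) and (4,3.2): same aspect, so g = 0.8 exactly
  f <- makeEllipseFiber(5, 4, 0.8)
  expect_equal(gRatio(f), 0.8, tolerance = 1e-9)
  expect_equal(fiberDiameter(f), 8, tolerance = 1e-2)
  expect_equal(axonDiameter(f), 6.4, tolerance = 1e-2)

  expect_error(MyelinatedFiber(inn, out), "smaller")

  set.seed(13)
  for (i in 1:1000) {
    a <- runif(1, 1, 8); b <- a * runif(1, 0.6, 1)
    g <- runif(1, 0.4, 0.9)
    f <- makeEllipseFiber(a, b, g, n = 128L)
    expect_true(gRatio(f) > 0 && gRatio(f) < 1)
  }
})

test_that("fascicle summary reproduces the annulus and generator counts", {
  outer <- Contour(regularPolygon(1024, 100), "perineurium_outer", "F1.PO")
  inner <- Contour(regularPolygon(1024, 90), "perineurium_inner", "F1.PI")
  fs <- fascicleSummary(Fascicle("F1", outer, inner))
  expect_equal(fs$fascicleArea, 10000 * pi, tolerance = 1e-4)
  expect_equal(fs$endoneuriumArea, 8100 * pi, tolerance = 1e-4)
  expect_equal(fs$endoFascicleRatio, 0.81, tolerance = 1e-9)
  expect_false(fs$hasSubfascicles)
  expect_gt(fs$perineuriumArea, 0)

  # generator-known counts (large-fascicle composition)
  gen <- presetSection("large-fascicle", seed = 2)
  fs2 <- fascicleSummary(gen$section@fascicles[[1]])
  expect_equal(fs2$nMyelinated, 221)
  expect_equal(fs2$nUnmyelinated, 467)

  gen3 <- threeSubfascicleSection(6L, 9L, seed = 21)
  expect_true(fascicleSummary(gen3$section@fascicles[[1]])$hasSubfascicles)
})

test_that("size distribution counts, modality and peak locations", {
  s1 <- sizeDistribution(c(1, 1, 1), 0.5)
  expect_equal(sum(s1$counts), 3)
  expect_equal(sum(s1$counts > 0), 1)
  expect_equal(s1$counts[s1$counts > 0], 3)
  expect_equal(s1$modality, 1)

  set.seed(19)
  d <- c(rnorm(500, 2.0, 0.25), rnorm(200, 9.5, 0.75))
  s2 <- sizeDistribution(d, 0.5)
  expect_equal(s2$modality, 2)
  expect_true(s2$peaks[1] >= 1.5 && s2$peaks[1] <= 2.5)
  expect_true(s2$peaks[2] >= 8 && s2$peaks[2] <= 11)

  for (n in c(1, 7, 100)) {
    x <- runif(n, 0, 12)
    expect_equal(sum(sizeDistribution(x, 1)$counts), n)
  }
  expect_error(sizeDistribution(numeric(), 1), "empty")
  expect_error(sizeDistribution(1, 0), "binWidth")
})

test_that("metrics are rigid-motion invariant and scale-covariant", {
  set.seed(23)
  for (i in 1:25) {
    v <- randomStarPolygon(20L)
    sm <- shapeMetrics(v)
    vt <- sweep(rotatePts(v, runif(1, 0, 2 * pi)), 2,
                runif(2, -100, 100), "+")
    smt <- shapeMetrics(vt)
    for (col in names(sm))
      expect_equal(smt[[col]], sm[[col]], tolerance = 1e-8)

    s <- runif(1, 0.1, 10)
    sms <- shapeMetrics(v * s)
    expect_equal(sms$area, sm$area * s^2, tolerance = 1e-9)
    expect_equal(sms$perimeter, sm$perimeter * s, tolerance = 1e-9)
    for (col in c("shapeFactor", "formFactor", "aspectRatio",
                  "compactness", "roundness"))
      expect_equal(sms[[col]], sm[[col]], tolerance = 1e-9)
  }
  # G-ratio is scale-free: same fiber at two scales
  f1 <- makeEllipseFiber(3, 2.4, 0.7, n = 256L)
  f2 <- makeEllipseFiber(30, 24, 0.7, n = 256L)
  expect_equal(gRatio(f1), gRatio(f2), tolerance = 1e-9)
})

test_that("sub-fascicle fraction arithmetic", {
  fr <- subfascicleFraction(rep(c(TRUE, FALSE), c(49, 268)))
  expect_equal(fr$count, 49)
  expect_equal(fr$total, 317)
  expect_equal(round(fr$percent, 1), 15.5)
})
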