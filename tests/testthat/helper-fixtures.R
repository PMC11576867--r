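# Shared fixtures. All randomized helpers draw from the current RNG stream;
# tests fix seeds with withr::local_seed() or set.seed().

# rigid rotation about the origin
rotatePts <- function(v, theta) {
  ca <- cos(theta); sa <- sin(theta)
  cbind(v[, 1] * ca - v[, 2] * sa, v[, 1] * sa + v[, 2] * ca)
}

# random star-shaped (hence simple) polygon around the origin
randomStarPolygon <- function(nVert = 24L, rRange = c(0.5, 2)) {
  th <- sort(runif(nVert, 0, 2 * pi))
  r <- runif(nVert, rRange[1], rRange[2])
  cbind(r * cos(th), r * sin(th))
}

# independent Ramanujan-II ellipse perimeter (oracle-side copy)
ramanujanPerimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# high-resolution ellipse-pair myelinated fiber (confocal same-aspect shapes,
# so the G-ratio is the scale factor exactly)
makeEllipseFiber <- function(a, b, g, n = 2048L, id = "m1") {
  outer <- Contour(ellipsePolygon(n, a, b), "myelin_outer",
                   paste0(id, ":out"))
  inner <- Contour(ellipsePolygon(n, a * g, b * g), "myelin_inner",
                   paste0(id, ":in"), paste0(id, ":out"))
  MyelinatedFiber(outer, inner)
}

# small synthetic section with three sub-fascicles for superposition tests
threeSubfascicleSection <- function(nM, nUM, seed) {
  generateCrossSection(
    sectionSpec(1L, nSubfascicles = 3L, seed = seed),
    populationSpec(nMyelinated = nM, nUnmyelinated = nUM, seed = seed))
}
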