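## S4 classes for the nerve cross-section domain model and the recording /
## fiber-model configuration. Validity methods check structural sanity only;
## the scientific invariants are checked (and reported, never thrown) by
## validateCrossSection().

.CONTOUR_ROLES <- c("perineurium_outer", "perineurium_inner",
                    "subfascicle_perineurium", "myelin_outer", "myelin_inner",
                    "unmyelinated_axon", "schwann_nucleus")

#' Contour: an ordered planar vertex list with a semantic role
#'
#' A closed polygon (terminal vertex not repeated) in micrometres with a role
#' drawn from the segmentation vocabulary: perineurium outer/inner,
#' sub-fascicle perineurium, myelin outer/inner, unmyelinated axon outline,
#' or Schwann-cell nucleus. Vertex order is normalized counter-clockwise
#' (positive signed area) on construction; a duplicated terminal vertex is
#' dropped.
#'
#' @slot role character; one of the role vocabulary.
#' @slot vertices n x 2 numeric matrix (x, y) in micrometres.
#' @slot entityId opaque identifier, unique within a cross-section.
#' @slot parentId optional identifier linking an inner contour to its outer
#'   contour (myelin) or a sub-fascicle to its parent fascicle; `NA` if none.
#' @export
setClass("Contour", representation(
  role = "character", vertices = "matrix",
  entityId = "character", parentId = "character"))

setValidity("Contour", function(object) {
  msg <- character()
  if (length(object@role) != 1L || !(object@role %in% .CONTOUR_ROLES))
    msg <- c(msg, sprintf("role must be one of: %s",
                          paste(.CONTOUR_ROLES, collapse = ", ")))
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L)
    msg <- c(msg, "vertices must be a numeric matrix with 2 columns")
  else {
    if (nrow(v) < 3L) msg <- c(msg, "a contour needs at least 3 vertices")
    if (any(!is.finite(v))) msg <- c(msg, "vertices must be finite")
  }
  if (length(object@entityId) != 1L || is.na(object@entityId))
    msg <- c(msg, "entityId must be a single non-NA string")
  if (length(object@parentId) != 1L)
    msg <- c(msg, "parentId must be length 1 (possibly NA)")
  if (length(msg)) msg else TRUE
})

#' Construct a Contour
#'
#' Drops a duplicated terminal vertex and reverses clockwise rings so the
#' stored polygon always has positive signed area.
#'
#' @param vertices n x 2 numeric matrix (x, y) in micrometres.
#' @param role contour role, see [`Contour-class`].
#' @param entityId identifier string.
#' @param parentId optional parent identifier.
#' @return A [`Contour-class`] object.
#' @export
#' @examples
#' Contour(regularPolygon(32, 5), "unmyelinated_axon", "u1")
Contour <- function(vertices, role, entityId, parentId = NA_character_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  n <- nrow(vertices)
  if (n >= 2L && isTRUE(all(vertices[1L, ] == vertices[n, ])))
    vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) >= 3L && polygonSignedArea(vertices) < 0)
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  methods::new("Contour", role = as.character(role), vertices = vertices,
               entityId = as.character(entityId),
               parentId = as.character(parentId))
}

#' Myelinated fiber: paired myelin outer/inner contours with SAE morphometry
#'
#' Derived quantities (shape-adjusted-ellipse corrected fiber and axon
#' diameters, myelin thickness, G-ratio, centroid) are computed at
#' construction from the two contours.
#'
#' @slot outer,inner [`Contour-class`] with roles myelin_outer / myelin_inner.
#' @slot fiberDiameter,axonDiameter SAE-corrected diameters, micrometres.
#' @slot myelinThickness (fiber - axon) / 2, micrometres.
#' @slot gRatio axon diameter / fiber diameter, dimensionless.
#' @slot centroid area centroid of the outer contour, micrometres.
#' @export
setClass("MyelinatedFiber", representation(
  outer = "Contour", inner = "Contour",
  fiberDiameter = "numeric", axonDiameter = "numeric",
  myelinThickness = "numeric", gRatio = "numeric", centroid = "numeric"))

#' Unmyelinated fiber: a single axon outline with SAE diameter
#'
#' @slot outline [`Contour-class`] with role unmyelinated_axon.
#' @slot axonDiameter SAE-corrected diameter, micrometres.
#' @slot centroid area centroid, micrometres.
#' @export
setClass("UnmyelinatedFiber", representation(
  outline = "Contour", axonDiameter = "numeric", centroid = "numeric"))

#' Fascicle: perineurium contours, sub-fascicles and resident fibers
#'
#' @slot id fascicle identifier.
#' @slot outer,inner perineurium outer/inner [`Contour-class`] objects (for a
#'   sub-fascicle both carry role subfascicle_perineurium).
#' @slot subfascicles list of `Fascicle` objects.
#' @slot myelinated list of [`MyelinatedFiber-class`] directly in this
#'   compartment (fibers inside a sub-fascicle live in that sub-fascicle).
#' @slot unmyelinated list of [`UnmyelinatedFiber-class`].
#' @slot nuclei list of Schwann-cell nucleus [`Contour-class`] objects.
#' @export
setClass("Fascicle", representation(
  id = "character", outer = "Contour", inner = "Contour",
  subfascicles = "list", myelinated = "list", unmyelinated = "list",
  nuclei = "list"))

#' Nerve cross-section: donor metadata plus fascicles
#'
#' @slot donorId donor identifier.
#' @slot side "left", "right" or "unknown".
#' @slot sex "male", "female" or "unknown".
#' @slot fascicles list of [`Fascicle-class`] objects.
#' @export
setClass("NerveCrossSection", representation(
  donorId = "character", side = "character", sex = "character",
  fascicles = "list"))

setValidity("NerveCrossSection", function(object) {
  msg <- character()
  if (!(object@side %in% c("left", "right", "unknown")))
    msg <- c(msg, "side must be left, right or unknown")
  if (!(object@sex %in% c("male", "female", "unknown")))
    msg <- c(msg, "sex must be male, female or unknown")
  if (!all(vapply(object@fascicles, methods::is, logical(1L), "Fascicle")))
    msg <- c(msg, "fascicles must be a list of Fascicle objects")
  if (length(msg)) msg else TRUE
})

#' Construct a MyelinatedFiber from its two myelin contours
#'
#' Computes SAE-corrected diameters for both contours, the myelin thickness
#' `(fiber - axon) / 2` and the G-ratio `axon / fiber`.
#'
#' @param outer,inner [`Contour-class`] objects (roles myelin_outer and
#'   myelin_inner).
#' @return A [`MyelinatedFiber-class`] object.
#' @export
#' @examples
#' out <- Contour(regularPolygon(64, 5), "myelin_outer", "m1:out")
#' inn <- Contour(regularPolygon(64, 3.5), "myelin_inner", "m1:in", "m1:out")
#' gRatio(MyelinatedFiber(out, inn))
MyelinatedFiber <- function(outer, inner) {
  mo <- contourMeasures(outer)
  mi <- contourMeasures(inner)
  fd <- saeDiameter(mo[["area"]], mo[["perimeter"]])
  ad <- saeDiameter(mi[["area"]], mi[["perimeter"]])
  if (ad >= fd)
    stop("axon SAE diameter (", signif(ad, 6), ") must be smaller than the ",
         "fiber SAE diameter (", signif(fd, 6), ") for ", outer@entityId)
  methods::new("MyelinatedFiber", outer = outer, inner = inner,
               fiberDiameter = fd, axonDiameter = ad,
               myelinThickness = (fd - ad) / 2, gRatio = ad / fd,
               centroid = polygonCentroid(outer@vertices))
}

#' Construct an UnmyelinatedFiber from its axon outline
#'
#' @param outline [`Contour-class`] with role unmyelinated_axon.
#' @return An [`UnmyelinatedFiber-class`] object.
#' @export
UnmyelinatedFiber <- function(outline) {
  m <- contourMeasures(outline)
  methods::new("UnmyelinatedFiber", outline = outline,
               axonDiameter = saeDiameter(m[["area"]], m[["perimeter"]]),
               centroid = polygonCentroid(outline@vertices))
}

#' Construct a Fascicle
#'
#' @param id fascicle identifier.
#' @param outer,inner perineurium contours.
#' @param subfascicles list of `Fascicle`.
#' @param myelinated,unmyelinated fiber lists.
#' @param nuclei list of nucleus contours.
#' @return A [`Fascicle-class`] object.
#' @export
Fascicle <- function(id, outer, inner, subfascicles = list(),
                     myelinated = list(), unmyelinated = list(),
                     nuclei = list()) {
  methods::new("Fascicle", id = as.character(id), outer = outer, inner = inner,
               subfascicles = subfascicles, myelinated = myelinated,
               unmyelinated = unmyelinated, nuclei = nuclei)
}

#' Construct a NerveCrossSection
#'
#' @param fascicles list of [`Fascicle-class`] objects.
#' @param donorId donor identifier.
#' @param side "left", "right" or "unknown".
#' @param sex "male", "female" or "unknown".
#' @return A [`NerveCrossSection-class`] object.
#' @export
NerveCrossSection <- function(fascicles = list(), donorId = "unknown",
                              side = "unknown", sex = "unknown") {
  methods::new("NerveCrossSection", donorId = as.character(donorId),
               side = side, sex = sex, fascicles = fascicles)
}

## ---- recording / fiber-model configuration ----

#' Fiber model parameters for action potential prediction
#'
#' Encodes the velocity, amplitude and duration laws used to turn a fiber's
#' SAE diameter into a single-fiber action potential: myelinated conduction
#' velocity `v = kMyelinated * D` (m/s, D in micrometres), unmyelinated
#' `v = cUnmyelinated * d^alphaUnmyelinated`; SFAP peak magnitude
#' proportional to diameter^ampExp (separate exponents per category);
#' characteristic waveform width `durationScale / v` milliseconds.
#'
#' @slot kMyelinated m/s per micrometre (default 6).
#' @slot cUnmyelinated m/s per micrometre^alpha (default 1.7).
#' @slot alphaUnmyelinated dimensionless exponent in (0, 1.5] (default 0.5).
#' @slot ampExpMyelinated,ampExpUnmyelinated amplitude exponents (2 and 1).
#' @slot template "gauss_second_derivative" or "biphasic_sine".
#' @slot durationScale ms * (m/s) (default 0.3).
#' @export
setClass("FiberModelParams", representation(
  kMyelinated = "numeric", cUnmyelinated = "numeric",
  alphaUnmyelinated = "numeric", ampExpMyelinated = "numeric",
  ampExpUnmyelinated = "numeric", template = "character",
  durationScale = "numeric"))

setValidity("FiberModelParams", function(object) {
  msg <- character()
  pos <- c(kMyelinated = object@kMyelinated, cUnmyelinated = object@cUnmyelinated,
           ampExpMyelinated = object@ampExpMyelinated,
           ampExpUnmyelinated = object@ampExpUnmyelinated,
           durationScale = object@durationScale)
  if (any(pos <= 0)) msg <- c(msg, "all coefficients must be > 0")
  if (object@alphaUnmyelinated <= 0 || object@alphaUnmyelinated > 1.5)
    msg <- c(msg, "alphaUnmyelinated must be in (0, 1.5]")
  if (!(object@template %in% c("gauss_second_derivative", "biphasic_sine")))
    msg <- c(msg, "template must be gauss_second_derivative or biphasic_sine")
  if (length(msg)) msg else TRUE
})

#' @rdname FiberModelParams-class
#' @param kMyelinated,cUnmyelinated,alphaUnmyelinated velocity-law parameters.
#' @param ampExpMyelinated,ampExpUnmyelinated amplitude exponents.
#' @param template SFAP template name.
#' @param durationScale waveform width scale, ms * (m/s).
#' @return A `FiberModelParams` object.
#' @export
fiberModelParams <- function(kMyelinated = 6, cUnmyelinated = 1.7,
                             alphaUnmyelinated = 0.5, ampExpMyelinated = 2,
                             ampExpUnmyelinated = 1,
                             template = c("gauss_second_derivative",
                                          "biphasic_sine"),
                             durationScale = 0.3) {
  methods::new("FiberModelParams", kMyelinated = kMyelinated,
               cUnmyelinated = cUnmyelinated,
               alphaUnmyelinated = alphaUnmyelinated,
               ampExpMyelinated = ampExpMyelinated,
               ampExpUnmyelinated = ampExpUnmyelinated,
               template = match.arg(template), durationScale = durationScale)
}

#' Cuff recording configuration
#'
#' @slot mode "differential" (bipolar cuff: proximal contact minus distal) or
#'   "single_ended".
#' @slot conductionDistance stimulating cathode to first recording contact, mm.
#' @slot electrodeSpacing inter-electrode distance within the cuff, mm.
#' @slot cuffInnerDiameter cuff inner diameter, mm (metadata only).
#' @slot sampleRate sampling rate, kHz.
#' @slot window recording window, ms; `NA` for automatic sizing.
#' @export
setClass("RecordingConfig", representation(
  mode = "character", conductionDistance = "numeric",
  electrodeSpacing = "numeric", cuffInnerDiameter = "numeric",
  sampleRate = "numeric", window = "numeric"))

setValidity("RecordingConfig", function(object) {
  msg <- character()
  if (!(object@mode %in% c("differential", "single_ended")))
    msg <- c(msg, "mode must be differential or single_ended")
  if (object@conductionDistance <= 0)
    msg <- c(msg, "conductionDistance must be > 0")
  if (object@mode == "differential" && object@electrodeSpacing <= 0)
    msg <- c(msg, "electrodeSpacing must be > 0 in differential mode")
  if (object@electrodeSpacing < 0)
    msg <- c(msg, "electrodeSpacing must be >= 0")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname RecordingConfig-class
#' @param mode recording mode.
#' @param conductionDistance mm.
#' @param electrodeSpacing mm.
#' @param cuffInnerDiameter mm, metadata only.
#' @param sampleRate kHz.
#' @param window ms, `NA` = auto.
#' @return A `RecordingConfig` object.
#' @export
#' @examples
#' recordingConfig(conductionDistance = 10, electrodeSpacing = 2)
recordingConfig <- function(mode = c("differential", "single_ended"),
                            conductionDistance = 10, electrodeSpacing = 2,
                            cuffInnerDiameter = 0.5, sampleRate = 100,
                            window = NA_real_) {
  methods::new("RecordingConfig", mode = match.arg(mode),
               conductionDistance = conductionDistance,
               electrodeSpacing = electrodeSpacing,
               cuffInnerDiameter = cuffInnerDiameter,
               sampleRate = sampleRate, window = as.numeric(window))
}

#' Single-fiber action potential
#'
#' @slot diameter SAE fiber diameter, micrometres.
#' @slot myelinated logical.
#' @slot velocity conduction velocity, m/s.
#' @slot latency arrival at the first recording contact, ms.
#' @slot time time grid, ms.
#' @slot samples waveform, arbitrary amplitude units.
#' @export
setClass("SFAP", representation(
  diameter = "numeric", myelinated = "logical", velocity = "numeric",
  latency = "numeric", time = "numeric", samples = "numeric"))

#' Compound nerve action potential prediction
#'
#' @slot time uniform time grid, ms.
#' @slot total summed trace over all fibers.
#' @slot perBin matrix of per-diameter-bin traces (columns named
#'   "M:[lo,hi)" / "UM:[lo,hi)"); rowSums equal `total`.
#' @slot peaks data.frame (latency_ms, amplitude, polarity).
#' @slot rec the [`RecordingConfig-class`] used.
#' @slot nFibers number of fibers summed.
#' @export
setClass("CNAPResult", representation(
  time = "numeric", total = "numeric", perBin = "matrix",
  peaks = "data.frame", rec = "RecordingConfig", nFibers = "integer"))

#' Diameter binning of a fiber population
#'
#' @slot edges strictly increasing bin edges, micrometres (2 to 6 values);
#'   bins are right-open except the last, which is closed.
#' @slot mode "auto" (variance-minimizing dynamic program) or "manual".
#' @slot labels bin labels.
#' @export
setClass("FiberBinning", representation(
  edges = "numeric", mode = "character", labels = "character"))

setValidity("FiberBinning", function(object) {
  msg <- character()
  if (length(object@edges) < 2L || length(object@edges) > 6L)
    msg <- c(msg, "edges must contain 2-6 values (at most 5 bins)")
  if (any(diff(object@edges) <= 0))
    msg <- c(msg, "edges must be strictly increasing")
  if (length(object@labels) != length(object@edges) - 1L)
    msg <- c(msg, "need one label per bin")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour <%s> role=%s, %d vertices, area %.4g um^2\n",
              object@entityId, object@role, nrow(object@vertices),
              abs(polygonSignedArea(object@vertices))))
})

setMethod("show", "MyelinatedFiber", function(object) {
  cat(sprintf(
    "MyelinatedFiber <%s> D=%.3g um, d=%.3g um, g=%.3f, myelin %.3g um\n",
    object@outer@entityId, object@fiberDiameter, object@axonDiameter,
    object@gRatio, object@myelinThickness))
})

setMethod("show", "UnmyelinatedFiber", function(object) {
  cat(sprintf("UnmyelinatedFiber <%s> d=%.3g um\n",
              object@outline@entityId, object@axonDiameter))
})

setMethod("show", "Fascicle", function(object) {
  cat(sprintf(
    "Fascicle <%s>: %d myelinated, %d unmyelinated, %d sub-fascicle(s)\n",
    object@id, length(object@myelinated), length(object@unmyelinated),
    length(object@subfascicles)))
})

setMethod("show", "NerveCrossSection", function(object) {
  nf <- vapply(object@fascicles, function(f)
    c(length(f@myelinated) + sum(vapply(f@subfascicles, function(s)
        length(s@myelinated), integer(1L))),
      length(f@unmyelinated) + sum(vapply(f@subfascicles, function(s)
        length(s@unmyelinated), integer(1L)))), numeric(2L))
  if (!length(object@fascicles)) nf <- matrix(0, 2, 1)
  cat(sprintf(
    "NerveCrossSection donor=%s side=%s sex=%s: %d fascicle(s), %d M + %d UM fibers\n",
    object@donorId, object@side, object@sex, length(object@fascicles),
    sum(nf[1L, ]), sum(nf[2L, ])))
})

setMethod("show", "CNAPResult", function(object) {
  cat(sprintf(
    "CNAPResult: %d fibers, %d samples @ %g kHz, %d bin trace(s), %d peak(s)\n",
    object@nFibers, length(object@time), object@rec@sampleRate,
    ncol(object@perBin), nrow(object@peaks)))
})

setMethod("show", "RecordingConfig", function(object) {
  cat(sprintf(
    "RecordingConfig: %s, d=%g mm, spacing=%g mm, %g kHz, window=%s ms\n",
    object@mode, object@conductionDistance, object@electrodeSpacing,
    object@sampleRate,
    if (is.na(object@window)) "auto" else format(object@window)))
})

setMethod("show", "FiberModelParams", function(object) {
  cat(sprintf(
    "FiberModelParams: v_M=%g*D, v_UM=%g*d^%g, amp ~ D^%g / d^%g, %s, width=%g/v ms\n",
    object@kMyelinated, object@cUnmyelinated, object@alphaUnmyelinated,
    object@ampExpMyelinated, object@ampExpUnmyelinated, object@template,
    object@durationScale))
})

setMethod("show", "FiberBinning", function(object) {
  cat(sprintf("FiberBinning (%s): %s\n", object@mode,
              paste(signif(object@edges, 4), collapse = " | ")))
})
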