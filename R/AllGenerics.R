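## Accessor generics. Slot access from user code should go through these.

#' @name accessors
#' @title Accessors for the nerve cross-section domain objects
#' @param x a domain object.
#' @return The corresponding slot value.
#' @examples
#' cn <- Contour(regularPolygon(16, 2), "unmyelinated_axon", "u1")
#' contourRole(cn); nrow(vertices(cn))
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setMethod("vertices", "Contour", function(x) x@vertices)

#' @rdname accessors
#' @export
setGeneric("contourRole", function(x) standardGeneric("contourRole"))
#' @rdname accessors
#' @export
setMethod("contourRole", "Contour", function(x) x@role)

#' @rdname accessors
#' @export
setGeneric("entityId", function(x) standardGeneric("entityId"))
#' @rdname accessors
#' @export
setMethod("entityId", "Contour", function(x) x@entityId)
#' @rdname accessors
#' @export
setMethod("entityId", "MyelinatedFiber",
          function(x) sub(":out$", "", x@outer@entityId))
#' @rdname accessors
#' @export
setMethod("entityId", "UnmyelinatedFiber", function(x) x@outline@entityId)
#' @rdname accessors
#' @export
setMethod("entityId", "Fascicle", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("fiberDiameter", function(x) standardGeneric("fiberDiameter"))
#' @rdname accessors
#' @export
setMethod("fiberDiameter", "MyelinatedFiber", function(x) x@fiberDiameter)

#' @rdname accessors
#' @export
setGeneric("axonDiameter", function(x) standardGeneric("axonDiameter"))
#' @rdname accessors
#' @export
setMethod("axonDiameter", "MyelinatedFiber", function(x) x@axonDiameter)
#' @rdname accessors
#' @export
setMethod("axonDiameter", "UnmyelinatedFiber", function(x) x@axonDiameter)

#' @rdname accessors
#' @export
setGeneric("myelinThickness", function(x) standardGeneric("myelinThickness"))
#' @rdname accessors
#' @export
setMethod("myelinThickness", "MyelinatedFiber", function(x) x@myelinThickness)

#' @rdname accessors
#' @export
setGeneric("gRatio", function(x) standardGeneric("gRatio"))
#' @rdname accessors
#' @export
setMethod("gRatio", "MyelinatedFiber", function(x) x@gRatio)

#' @rdname accessors
#' @export
setGeneric("fiberCentroid", function(x) standardGeneric("fiberCentroid"))
#' @rdname accessors
#' @export
setMethod("fiberCentroid", "MyelinatedFiber", function(x) x@centroid)
#' @rdname accessors
#' @export
setMethod("fiberCentroid", "UnmyelinatedFiber", function(x) x@centroid)

#' @rdname accessors
#' @export
setGeneric("fascicles", function(x) standardGeneric("fascicles"))
#' @rdname accessors
#' @export
setMethod("fascicles", "NerveCrossSection", function(x) x@fascicles)

#' @rdname accessors
#' @export
setGeneric("subfascicles", function(x) standardGeneric("subfascicles"))
#' @rdname accessors
#' @export
setMethod("subfascicles", "Fascicle", function(x) x@subfascicles)

#' @rdname accessors
#' @export
setGeneric("myelinated", function(x) standardGeneric("myelinated"))
#' @rdname accessors
#' @export
setMethod("myelinated", "Fascicle", function(x) x@myelinated)

#' @rdname accessors
#' @export
setGeneric("unmyelinated", function(x) standardGeneric("unmyelinated"))
#' @rdname accessors
#' @export
setMethod("unmyelinated", "Fascicle", function(x) x@unmyelinated)

#' @rdname accessors
#' @export
setGeneric("donorId", function(x) standardGeneric("donorId"))
#' @rdname accessors
#' @export
setMethod("donorId", "NerveCrossSection", function(x) x@donorId)

#' @rdname accessors
#' @export
setGeneric("nerveSide", function(x) standardGeneric("nerveSide"))
#' @rdname accessors
#' @export
setMethod("nerveSide", "NerveCrossSection", function(x) x@side)

#' @rdname accessors
#' @export
setGeneric("donorSex", function(x) standardGeneric("donorSex"))
#' @rdname accessors
#' @export
setMethod("donorSex", "NerveCrossSection", function(x) x@sex)

#' @rdname accessors
#' @export
setGeneric("cnapTime", function(x) standardGeneric("cnapTime"))
#' @rdname accessors
#' @export
setMethod("cnapTime", "CNAPResult", function(x) x@time)

#' @rdname accessors
#' @export
setGeneric("cnapTotal", function(x) standardGeneric("cnapTotal"))
#' @rdname accessors
#' @export
setMethod("cnapTotal", "CNAPResult", function(x) x@total)

#' @rdname accessors
#' @export
setGeneric("cnapPerBin", function(x) standardGeneric("cnapPerBin"))
#' @rdname accessors
#' @export
setMethod("cnapPerBin", "CNAPResult", function(x) x@perBin)

#' @rdname accessors
#' @export
setGeneric("cnapPeaks", function(x) standardGeneric("cnapPeaks"))
#' @rdname accessors
#' @export
setMethod("cnapPeaks", "CNAPResult", function(x) x@peaks)

#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setMethod("binEdges", "FiberBinning", function(x) x@edges)
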