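#' @rdname ClassProfileSet-class
#' @param x a \code{ClassProfileSet}
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname ClassProfileSet-class
#' @export
setGeneric("referenceLabel", function(x) standardGeneric("referenceLabel"))

#' @rdname ClassProfileSet-class
#' @export
setGeneric("profileLabels", function(x) standardGeneric("profileLabels"))

#' @rdname ClassProfileSet-class
#' @param label a cell-type label
#' @export
setGeneric("cystSizes", function(x, label) standardGeneric("cystSizes"))

#' @rdname SceneBundle-class
#' @param x a \code{SceneBundle}
#' @export
setGeneric("sceneChannels", function(x) standardGeneric("sceneChannels"))

#' @rdname SceneBundle-class
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))

#' @rdname SceneBundle-class
#' @export
setGeneric("sceneConfigOf", function(x) standardGeneric("sceneConfigOf"))

#' @rdname NucleusLabelMap-class
#' @param x a \code{NucleusLabelMap}
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname NucleusLabelMap-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname NucleusLabelMap-class
#' @export
setGeneric("nucleusCount", function(x) standardGeneric("nucleusCount"))

#' @rdname Cyst3D-class
#' @param x a \code{Cyst3D}
#' @export
setGeneric("cystCenters", function(x) standardGeneric("cystCenters"))

#' @rdname Cyst3D-class
#' @export
setGeneric("ballRadius", function(x) standardGeneric("ballRadius"))

#' @rdname Cyst3D-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

setMethod("profileTable", "ClassProfileSet", function(x) x@profiles)
setMethod("referenceLabel", "ClassProfileSet", function(x) x@reference)
setMethod("profileLabels", "ClassProfileSet", function(x) x@profiles$label)
setMethod("cystSizes", "ClassProfileSet", function(x, label) {
  if (!label %in% names(x@cystSizes)) stop("unknown label: ", label)
  x@cystSizes[[label]]
})

setMethod("sceneChannels", "SceneBundle", function(x) x@channels)
setMethod("sceneTruth", "SceneBundle", function(x) x@truth)
setMethod("sceneConfigOf", "SceneBundle", function(x) x@config)

setMethod("labelMatrix", "NucleusLabelMap", function(x) x@labels)
setMethod("pixelSize", "NucleusLabelMap", function(x) x@pixelSize)
setMethod("nucleusCount", "NucleusLabelMap",
          function(x) as.integer(max(0L, max(x@labels))))

setMethod("cystCenters", "Cyst3D", function(x) x@centers)
setMethod("ballRadius", "Cyst3D", function(x) x@ballRadius)
setMethod("nCells", "Cyst3D", function(x) x@nCells)
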