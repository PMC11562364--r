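#' @name CIlocate-accessors
#' @title Accessor generics for CIlocate classes
#' @description Small accessor generics used across the package's S4
#'   classes; each has methods documented with its class.
#' @param x an object of one of the package's S4 classes.
#' @return The slot value (see the class documentation).
NULL

#' @rdname CIlocate-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname CIlocate-accessors
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))
#' @rdname CIlocate-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname CIlocate-accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname CIlocate-accessors
#' @export
setGeneric("nElectrodes", function(x) standardGeneric("nElectrodes"))
#' @rdname CIlocate-accessors
#' @export
setGeneric("gapDistances", function(x) standardGeneric("gapDistances"))
#' @rdname CIlocate-accessors
#' @export
setGeneric("pathNodes", function(x) standardGeneric("pathNodes"))
#' @rdname CIlocate-accessors
#' @export
setGeneric("pathCost", function(x) standardGeneric("pathCost"))
#' @rdname CIlocate-accessors
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' @rdname CIlocate-accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @rdname CIlocate-accessors
#' @export
setMethod("worldOrigin", "CTVolume", function(x) x@origin)
#' @rdname CIlocate-accessors
#' @export
setMethod("intensities", "CTVolume", function(x) x@data)
#' @rdname CIlocate-accessors
#' @export
setMethod("intensities", "CandidateSet", function(x) x@intensity)
#' @rdname CIlocate-accessors
#' @export
setMethod("coords", "CandidateSet", function(x) x@coords)
#' @rdname CIlocate-accessors
#' @export
setMethod("nElectrodes", "EASpec", function(x) x@nElectrodes)
#' @rdname CIlocate-accessors
#' @export
setMethod("gapDistances", "EASpec", function(x) x@gapDistances)
#' @rdname CIlocate-accessors
#' @export
setMethod("pathNodes", "ElectrodePath", function(x) x@nodes)
#' @rdname CIlocate-accessors
#' @export
setMethod("pathCost", "ElectrodePath", function(x) x@cost)
#' @rdname CIlocate-accessors
#' @export
setMethod("isComplete", "ElectrodePath", function(x) x@complete)

#' @describeIn CTVolume dimensions of the intensity grid.
#' @param x a `CTVolume`.
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@data))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume %d x %d x %d voxels, spacing [%s] mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = ", ")))
  cat(sprintf("  origin [%s] mm, intensity range [%.4g, %.4g]\n",
              paste(format(object@origin, digits = 4), collapse = ", "),
              min(object@data), max(object@data)))
})

setMethod("show", "EASpec", function(object) {
  g <- object@gapDistances
  gaps <- if (length(unique(round(g, 6))) == 1L)
    sprintf("constant %.4g mm", g[1])
  else sprintf("%.4g-%.4g mm (apex-to-base)", min(g), max(g))
  cat(sprintf("EASpec \"%s\" (%s): %d electrodes", object@name,
              object@manufacturer, object@nElectrodes))
  if (object@nMarkers > 0L) cat(sprintf(" + %d marker", object@nMarkers))
  cat(sprintf(", gaps %s", gaps))
  if (object@apicalLowIntensity > 0L)
    cat(sprintf(", %d dim apical contacts", object@apicalLowIntensity))
  cat("\n")
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d candidate points", nrow(object@coords)))
  if (!is.na(object@alpha1))
    cat(sprintf(" (alpha1 = %.3g%%, cutoff = %.4g)", object@alpha1,
                object@cutoff))
  cat("\n")
})

setMethod("show", "ElectrodePath", function(object) {
  cat(sprintf("ElectrodePath: %d nodes, cost %.4f%s\n",
              nrow(object@nodes), object@cost,
              if (object@complete) "" else " [INCOMPLETE]"))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: L_a = %.3f mm, detection rate = %.1f%% (radius %.2g mm)\n",
              object@accuracy, object@detectionRate, object@radius))
  cat(sprintf("  conditional accuracy (detected only) = %.3f mm\n",
              object@conditionalAccuracy))
  cat(sprintf("  error classes: %s\n",
              if (length(object@errorLabels)) paste(object@errorLabels,
                                                    collapse = ", ")
              else "none"))
})
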