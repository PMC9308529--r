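#' Accessors for the package's S4 containers
#'
#' `labelMatrix()` returns the integer label grid of a [TissueLabelMap-class];
#' `tempMatrix()` the temperature grid of a [TemperatureField-class];
#' `pixelMatrix()` the normalized pixels of a [ThermalImage-class];
#' `spacing()` the pixel size in mm; `imageMask()` the aligned binary lesion
#' mask (or `NULL`); `sourceRange()` the (min, max) temperatures used in
#' normalization; `iterations()`, `converged()` and `finalDelta()` the solver
#' convergence metadata.
#'
#' @param x one of the package's S4 objects.
#' @return The slot contents (see above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("labelLegend", function(x) standardGeneric("labelLegend"))
#' @rdname accessors
#' @export
setGeneric("tempMatrix", function(x) standardGeneric("tempMatrix"))
#' @rdname accessors
#' @export
setGeneric("iterations", function(x) standardGeneric("iterations"))
#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("finalDelta", function(x) standardGeneric("finalDelta"))
#' @rdname accessors
#' @export
setGeneric("pixelMatrix", function(x) standardGeneric("pixelMatrix"))
#' @rdname accessors
#' @export
setGeneric("imageMask", function(x) standardGeneric("imageMask"))
#' @rdname accessors
#' @export
setGeneric("sourceRange", function(x) standardGeneric("sourceRange"))

#' @rdname accessors
setMethod("labelMatrix", "TissueLabelMap", function(x) x@labels)
#' @rdname accessors
setMethod("spacing", "TissueLabelMap", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "TemperatureField", function(x) x@spacing)
#' @rdname accessors
setMethod("labelLegend", "TissueLabelMap", function(x) x@legend)
#' @rdname accessors
setMethod("tempMatrix", "TemperatureField", function(x) x@temps)
#' @rdname accessors
setMethod("iterations", "TemperatureField", function(x) x@iterations)
#' @rdname accessors
setMethod("converged", "TemperatureField", function(x) x@converged)
#' @rdname accessors
setMethod("finalDelta", "TemperatureField", function(x) x@finalDelta)
#' @rdname accessors
setMethod("pixelMatrix", "ThermalImage", function(x) x@pixels)
#' @rdname accessors
setMethod("imageMask", "ThermalImage",
          function(x) if (length(x@mask)) x@mask else NULL)
#' @rdname accessors
setMethod("sourceRange", "ThermalImage", function(x) x@sourceRange)

setMethod("show", "TissueLabelMap", function(object) {
  lab <- object@labels
  counts <- table(factor(lab, levels = object@legend,
                         labels = names(object@legend)))
  cat(sprintf("TissueLabelMap: %d x %d pixels, %.3g mm spacing\n",
              nrow(lab), ncol(lab), object@spacing))
  cat("  pixel counts:",
      paste(sprintf("%s=%d", names(counts), as.integer(counts)),
            collapse = ", "), "\n")
})

setMethod("show", "TemperatureField", function(object) {
  cat(sprintf(paste0("TemperatureField: %d x %d pixels, range ",
                     "[%.4f, %.4f] degC\n"),
              nrow(object@temps), ncol(object@temps),
              min(object@temps), max(object@temps)))
  cat(sprintf("  %d iterations, converged=%s, final delta %.3g degC\n",
              object@iterations, object@converged, object@finalDelta))
})

setMethod("show", "ThermalImage", function(object) {
  cat(sprintf("ThermalImage: %d x %d pixels in [0,1], source range [%.4f, %.4f] degC\n",
              nrow(object@pixels), ncol(object@pixels),
              object@sourceRange[1], object@sourceRange[2]))
  if (length(object@mask))
    cat(sprintf("  lesion mask: %d positive pixels\n", sum(object@mask)))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d (total %d)\n",
              object@tp, object@fp, object@tn, object@fn,
              object@tp + object@fp + object@tn + object@fn))
})
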