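#' @importFrom methods new validObject is setClass setValidity setGeneric
#'   setMethod slot
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils write.csv read.csv
NULL

#' Tissue label legend
#'
#' Fixed integer coding of the tissue classes used throughout the package:
#' background = 0, CSF = 1, GM = 2, WM = 3, penumbra = 4, infarct_core = 5.
#'
#' @return Named integer vector mapping tissue name to label integer.
#' @export
#' @examples
#' tissueLegend()
tissueLegend <- function() {
  c(background = 0L, CSF = 1L, GM = 2L, WM = 3L,
    penumbra = 4L, infarct_core = 5L)
}

#' TissueLabelMap: a 2D integer map of tissue classes
#'
#' Each pixel of the grid carries an integer tissue label (see
#' [tissueLegend()]). `spacing` is the isotropic pixel size in mm. The
#' `geometry` slot records the phantom construction parameters (ellipse
#' center, semi-axes and band radii) when the object was produced by
#' [generateBrainPhantom()], so that independent re-rasterization is possible.
#'
#' @slot labels integer matrix of tissue labels.
#' @slot spacing numeric(1), mm per pixel (isotropic).
#' @slot legend named integer vector, tissue name -> label.
#' @slot geometry list of phantom construction parameters (may be empty).
#'
#' @aliases TissueLabelMap-class
#' @export
setClass("TissueLabelMap",
  representation(labels = "matrix", spacing = "numeric",
                 legend = "integer", geometry = "list"),
  prototype(spacing = 2, legend = tissueLegend(), geometry = list()))

setValidity("TissueLabelMap", function(object) {
  msg <- character()
  lab <- object@labels
  if (length(lab) == 0L || nrow(lab) < 1L || ncol(lab) < 1L)
    msg <- c(msg, "label grid must be non-empty")
  if (!is.numeric(lab) || any(!is.finite(lab)) || any(lab != round(lab)))
    msg <- c(msg, "labels must be finite integers")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number (mm)")
  if (is.null(names(object@legend)) || any(!nzchar(names(object@legend))))
    msg <- c(msg, "legend must be a named integer vector")
  extra <- setdiff(unique(as.integer(lab)), object@legend)
  if (length(extra))
    msg <- c(msg, paste0("labels not in legend: ",
                         paste(extra, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a TissueLabelMap
#'
#' @param labels integer matrix of tissue labels.
#' @param spacing pixel size in mm (isotropic), default 2.
#' @param legend named integer vector; defaults to [tissueLegend()].
#' @param geometry optional list of construction metadata.
#' @return A [TissueLabelMap-class] object.
#' @export
TissueLabelMap <- function(labels, spacing = 2, legend = tissueLegend(),
                           geometry = list()) {
  storage.mode(labels) <- "integer"
  new("TissueLabelMap", labels = labels, spacing = spacing,
      legend = legend, geometry = geometry)
}

#' TemperatureField: a solved 2D temperature grid
#'
#' @slot temps numeric matrix of temperatures in degrees C.
#' @slot spacing numeric(1), mm per pixel.
#' @slot iterations integer, number of synchronous sweeps performed.
#' @slot converged logical, whether the max node-wise change fell below tol.
#' @slot finalDelta numeric, max absolute per-node change on the last sweep.
#' @slot tol numeric, the convergence tolerance used (degrees C).
#'
#' @aliases TemperatureField-class
#' @export
setClass("TemperatureField",
  representation(temps = "matrix", spacing = "numeric",
                 iterations = "integer", converged = "logical",
                 finalDelta = "numeric", tol = "numeric"))

setValidity("TemperatureField", function(object) {
  msg <- character()
  if (any(!is.finite(object@temps)))
    msg <- c(msg, "temperatures must all be finite")
  if (isTRUE(object@converged) && object@finalDelta >= object@tol)
    msg <- c(msg, "converged fields must have finalDelta < tol")
  if (length(msg)) msg else TRUE
})

#' ThermalImage: a normalized grayscale image with optional lesion mask
#'
#' Pixels lie in [0, 1]; `sourceRange` keeps the (min, max) temperatures used
#' for the min-max normalization so the field can be recovered.
#'
#' @slot pixels numeric matrix in [0, 1].
#' @slot sourceRange numeric(2), the (min, max) degrees C of the source field.
#' @slot mask matrix: binary lesion ground truth (0/1) aligned to `pixels`,
#'   or a 0x0 matrix when absent.
#' @slot seed integer, the noise RNG seed used upstream (NA when no noise).
#'
#' @aliases ThermalImage-class
#' @export
setClass("ThermalImage",
  representation(pixels = "matrix", sourceRange = "numeric",
                 mask = "matrix", seed = "integer"),
  prototype(mask = matrix(numeric(0), 0, 0), seed = NA_integer_))

setValidity("ThermalImage", function(object) {
  msg <- character()
  p <- object@pixels
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    msg <- c(msg, "pixels must be finite and within [0, 1]")
  if (length(object@sourceRange) != 2L)
    msg <- c(msg, "sourceRange must be length 2")
  if (length(object@mask) > 0L) {
    if (!identical(dim(object@mask), dim(p)))
      msg <- c(msg, "mask must have the same shape as pixels")
    if (any(!object@mask %in% c(0, 1)))
      msg <- c(msg, "mask must be binary (0/1)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ThermalImage
#'
#' @param pixels numeric matrix in [0, 1].
#' @param sourceRange numeric(2) (min, max) source temperatures, degrees C.
#' @param mask optional binary matrix aligned with `pixels`.
#' @param seed optional integer noise seed for provenance.
#' @return A [ThermalImage-class] object.
#' @export
ThermalImage <- function(pixels, sourceRange, mask = NULL, seed = NA) {
  if (is.null(mask)) mask <- matrix(numeric(0), 0, 0)
  new("ThermalImage", pixels = pixels, sourceRange = as.numeric(sourceRange),
      mask = mask, seed = as.integer(seed))
}

#' ConfusionCounts: pixel-level confusion matrix for a binary segmentation
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @aliases ConfusionCounts-class
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer",
                 tn = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(v < 0)) "counts must be non-negative" else TRUE
})
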